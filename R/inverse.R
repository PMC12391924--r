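#' @include AllClasses.R forward.R recording.R
NULL

#' Estimate the sensor covariance with diagonal loading
#'
#' Sample covariance over time (mean removed per sensor, divisor T-1), plus
#' diagonal loading of \code{loadingFraction * trace/S} — the standard
#' regularization that keeps beamformer filters well-conditioned for short
#' recordings.
#'
#' @param recording a \linkS4class{SensorRecording} with at least 2 samples.
#' @param loadingFraction diagonal loading as a fraction of the mean sensor
#'   variance (default 0.05).
#' @return a \linkS4class{Covariance}
#' @export
estimateCovariance <- function(recording, loadingFraction = 0.05) {
  stopifnot(is(recording, "SensorRecording"))
  M <- samples(recording)
  if (ncol(M) < 2L) stop("insufficient-data: need T >= 2 samples", call. = FALSE)
  C <- stats::cov(t(M))
  S <- nrow(C)
  C <- C + diag(loadingFraction * sum(diag(C)) / S, S)
  C <- (C + t(C)) / 2
  new("Covariance", matrix = C, loadingFraction = loadingFraction)
}

.solverSolution <- function(Q, method, hyper, scores = numeric(0), info = list()) {
  new("InverseSolution", amplitudes = Q, scores = scores, method = method,
      hyperparameters = hyper, info = info)
}

#' LCMV beamformer
#'
#' Linearly constrained minimum-variance spatial filtering: for each dipole
#' with leadfield column l, the filter \code{w = C^-1 l / (l' C^-1 l)}
#' minimizes output power subject to the unit-gain constraint
#' \code{w'l = 1}; the dipole's amplitude trace is \code{w'M}.
#'
#' @param leadfield a \linkS4class{Leadfield}.
#' @param covariance a positive-definite \linkS4class{Covariance} (use
#'   diagonal loading when estimated from short or noiseless data).
#' @param recording a \linkS4class{SensorRecording}.
#' @return an \linkS4class{InverseSolution} (method "lcmv")
#' @export
solveLCMV <- function(leadfield, covariance, recording) {
  stopifnot(is(leadfield, "Leadfield"), is(covariance, "Covariance"),
            is(recording, "SensorRecording"))
  L <- gain(leadfield); M <- samples(recording)
  Cinv <- tryCatch(solve(covariance@matrix),
                   error = function(e)
                     stop("numerical-conditioning: covariance is singular; ",
                          "re-estimate with diagonal loading > 0", call. = FALSE))
  A <- Cinv %*% L                       # S x D
  denom <- colSums(L * A)               # l' C^-1 l per dipole
  silent <- colSums(L^2) == 0           # zero columns have no defined filter
  if (any(denom[!silent] <= 0))
    stop("numerical-conditioning: non-positive filter normalization; ",
         "increase diagonal loading", call. = FALSE)
  denom[silent] <- 1
  Q <- crossprod(A, M) / denom          # D x T
  Q[silent, ] <- 0
  .solverSolution(Q, "lcmv",
                  list(loadingFraction = covariance@loadingFraction),
                  info = list(silentColumns = which(silent)))
}

#' Minimum-norm estimate
#'
#' Tikhonov-regularized least squares in sensor space:
#' \code{Q = L' (L L' + lambda I)^-1 M}, the minimum-L2-norm solution among
#' all exact fits as lambda -> 0.
#'
#' @param leadfield a \linkS4class{Leadfield}.
#' @param recording a \linkS4class{SensorRecording}.
#' @param lambda regularization (>= 0); NULL picks
#'   \code{0.05 * trace(L L') / S}.
#' @return an \linkS4class{InverseSolution} (method "mne")
#' @export
solveMNE <- function(leadfield, recording, lambda = NULL) {
  stopifnot(is(leadfield, "Leadfield"), is(recording, "SensorRecording"))
  L <- gain(leadfield); M <- samples(recording)
  G <- tcrossprod(L)
  if (is.null(lambda)) lambda <- 0.05 * sum(diag(G)) / nrow(G)
  if (lambda < 0) .stopInvalidConfig("lambda must be >= 0")
  K <- G + diag(lambda, nrow(G))
  sol <- tryCatch(solve(K, M),
                  error = function(e)
                    stop("singularity: L L' + lambda I is not invertible ",
                         "(rank-deficient gram matrix with lambda = 0)",
                         call. = FALSE))
  .solverSolution(crossprod(L, sol), "mne", list(lambda = lambda))
}

#' eLORETA: exact low-resolution electromagnetic tomography
#'
#' Weighted minimum-norm inverse whose diagonal depth weights are computed
#' by the fixed-point iteration
#' \code{w_i <- sqrt( l_i' (L W^-1 L' + alpha H)^+ l_i )}, iterated until
#' the largest relative weight change drops below \code{tol}. The weights
#' compensate depth bias, giving exact localization of single point sources
#' in the noiseless case. \code{H} is the identity here (average-reference
#' centering is an EEG concern).
#'
#' @param leadfield a \linkS4class{Leadfield}.
#' @param recording a \linkS4class{SensorRecording}.
#' @param alpha regularization (> 0); NULL picks
#'   \code{0.05 * trace(L L') / S}.
#' @param tol convergence tolerance on the relative weight change.
#' @param maxIter iteration cap; non-convergence returns the best iterate
#'   with a warning flag in \code{info}.
#' @return an \linkS4class{InverseSolution} (method "eloreta") with
#'   \code{info$converged} and \code{info$iterations}.
#' @export
solveELORETA <- function(leadfield, recording, alpha = NULL, tol = 1e-6,
                         maxIter = 100L) {
  stopifnot(is(leadfield, "Leadfield"), is(recording, "SensorRecording"))
  L <- gain(leadfield); M <- samples(recording)
  S <- nrow(L); D <- ncol(L)
  if (is.null(alpha)) alpha <- 0.05 * sum(L^2) / S
  if (alpha <= 0) .stopInvalidConfig("alpha must be > 0")
  w <- rep(1, D)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    Linvw <- sweep(L, 2, w, "/")              # L W^-1
    Minner <- .pinvSym(tcrossprod(Linvw, L) + diag(alpha, S))
    wNew <- sqrt(pmax(colSums(L * (Minner %*% L)), 0))
    wNew[wNew == 0] <- min(wNew[wNew > 0])    # guard silent columns
    delta <- max(abs(wNew - w) / w)
    w <- wNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("eLORETA did not converge in ", maxIter, " iterations")
  Linvw <- sweep(L, 2, w, "/")
  Minner <- .pinvSym(tcrossprod(Linvw, L) + diag(alpha, S))
  Q <- sweep(crossprod(L, Minner %*% M), 1, w, "/")
  .solverSolution(Q, "eloreta",
                  list(alpha = alpha, tol = tol, maxIter = maxIter),
                  info = list(converged = converged, iterations = iter,
                              weights = w))
}

#' Residual-variance single-dipole scan
#'
#' Fits each grid dipole alone by least squares
#' (\code{q_i = l_i' M / (l_i' l_i)}) and scores it by the fraction of
#' sensor-data power it leaves unexplained:
#' \code{RV_i = ||M - l_i q_i||_F^2 / ||M||_F^2}, in [0, 1]. The best dipole
#' is the argmin. Silent (all-zero) leadfield columns score 1 and are
#' flagged.
#'
#' @param leadfield a \linkS4class{Leadfield}.
#' @param recording a non-zero \linkS4class{SensorRecording}.
#' @return an \linkS4class{InverseSolution} (method "rv") whose
#'   \code{scores} hold the per-dipole residual variance and whose
#'   amplitudes are the per-dipole least-squares traces.
#' @export
solveRVScan <- function(leadfield, recording) {
  stopifnot(is(leadfield, "Leadfield"), is(recording, "SensorRecording"))
  L <- gain(leadfield); M <- samples(recording)
  normM2 <- sum(M^2)
  if (normM2 == 0) stop("recording is identically zero", call. = FALSE)
  l2 <- colSums(L^2)
  silent <- l2 == 0
  l2safe <- ifelse(silent, 1, l2)
  Q <- crossprod(L, M) / l2safe         # D x T least-squares traces
  # ||M - l q||^2 = ||M||^2 - ||l q||^2 for the LS fit
  rv <- pmin(pmax(1 - l2safe * rowSums(Q^2) / normM2, 0), 1)
  rv[silent] <- 1
  Q[silent, ] <- 0
  .solverSolution(Q, "rv", list(),
                  scores = rv,
                  info = list(best = which.min(rv),
                              silentColumns = which(silent)))
}
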