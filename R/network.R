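#' @include AllClasses.R network-layers.R training-set.R
NULL

#' Construct a network architecture configuration
#'
#' Defaults follow the reference architecture: 4 temporal convolution layers
#' with feature schedule 16-32-64-128 shared across sensors, batch
#' normalization between consecutive conv layers and a ReLU after each,
#' then 6 fully-connected ReLU layers of 500 nodes and a final linear layer
#' with one output per dipole. The kernel schedule must consume the window
#' exactly down to temporal extent 1; the default \code{c(5, 5, 3, 11)}
#' realizes 21 -> 17 -> 13 -> 11 -> 1 with a full-width last kernel.
#'
#' @param nSensors S, sensors per window.
#' @param nSources D, output dipoles.
#' @param W window length in samples (odd, default 21).
#' @param convFeatures per-layer feature counts (default 16, 32, 64, 128).
#' @param convKernels per-layer kernel lengths; NULL picks
#'   \code{c(5, 5, 3, <remaining extent>)} so the temporal axis collapses
#'   to 1.
#' @param fcLayers hidden fully-connected layers (default 6).
#' @param fcWidth nodes per hidden layer (default 500).
#' @return a \linkS4class{NetworkConfig}
#' @export
networkConfig <- function(nSensors, nSources, W = 21L,
                          convFeatures = c(16L, 32L, 64L, 128L),
                          convKernels = NULL,
                          fcLayers = 6L, fcWidth = 500L) {
  W <- as.integer(W)
  if (is.null(convKernels)) {
    nl <- length(convFeatures)
    convKernels <- integer(nl)
    ext <- W
    base <- c(5L, 5L, rep(3L, max(nl - 2L, 0L)))
    for (l in seq_len(nl)) {
      convKernels[l] <- if (l == nl) ext else min(base[l], ext - (nl - l))
      ext <- ext - convKernels[l] + 1L
    }
  }
  ext <- W
  exts <- integer(0)
  for (k in as.integer(convKernels)) { ext <- ext - k + 1L; exts <- c(exts, ext) }
  if (any(exts < 1L) || exts[length(exts)] != 1L)
    stop(sprintf(
      "invalid-architecture: conv kernel schedule must reduce W=%d to temporal extent 1; achieved extents: %s",
      W, paste(exts, collapse = " -> ")), call. = FALSE)
  new("NetworkConfig", W = W,
      convFeatures = as.integer(convFeatures),
      convKernels = as.integer(convKernels),
      fcLayers = as.integer(fcLayers), fcWidth = as.integer(fcWidth),
      nSensors = as.integer(nSensors), nSources = as.integer(nSources))
}

#' Construct training settings
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 1e-4, minibatches of 64, mean-squared-error loss.
#'
#' @param epochs passes over the training set.
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param seed RNG seed controlling initialization and shuffling.
#' @param valFraction fraction of examples held out for validation.
#' @return a \linkS4class{TrainConfig}
#' @export
trainConfig <- function(epochs = 10L, learningRate = 1e-4, batchSize = 64L,
                        seed = 1L, valFraction = 0.1) {
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), valFraction = valFraction,
      beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8)
}

#' Build an untrained network
#'
#' Allocates He-initialized parameters for the configured topology. The
#' result is a \linkS4class{TrainedModel} with identity scalers and an empty
#' training history; pass it to \code{\link{trainModel}}.
#'
#' @param config a \linkS4class{NetworkConfig}.
#' @param initSeed RNG seed for the weight draw.
#' @return a \linkS4class{TrainedModel} (untrained)
#' @export
buildNetwork <- function(config, initSeed = 1L) {
  stopifnot(is(config, "NetworkConfig"))
  params <- .withSeed(initSeed, .initParams(config))
  new("TrainedModel", params = params, config = config,
      inputMean = numeric(config@nSensors), inputSd = rep(1, config@nSensors),
      targetScale = 1,
      history = data.frame(epoch = integer(0), train = numeric(0),
                           val = numeric(0)))
}

#' Total trainable parameter count
#'
#' @param model a \linkS4class{TrainedModel}.
#' @return integer count over conv weights/biases, batch-norm scale/shift,
#'   and fully-connected weights/biases.
#' @export
nParameters <- function(model) {
  p <- model@params
  sum(vapply(p$conv, function(l) length(l$W) + length(l$b), numeric(1))) +
    sum(vapply(p$bn, function(l) length(l$gamma) + length(l$beta), numeric(1))) +
    sum(vapply(p$fc, function(l) length(l$W) + length(l$b), numeric(1)))
}

.standardizeWindows <- function(windows, mean, sd) {
  S <- dim(windows)[2]
  for (s in seq_len(S))
    windows[, s, ] <- (windows[, s, ] - mean[s]) / sd[s]
  windows
}

#' Train the network
#'
#' Minibatch Adam on mean-squared error. Inputs are standardized per sensor
#' and targets scaled to unit maximum absolute amplitude, with the constants
#' estimated on the training set and stored in the model for consistent
#' inference. Fully deterministic given \code{config@seed}.
#'
#' @param model an untrained or pre-trained \linkS4class{TrainedModel}.
#' @param trainSet a \linkS4class{TrainingSet}.
#' @param valSet optional \linkS4class{TrainingSet} for validation; when
#'   NULL and \code{valFraction > 0}, a split of \code{trainSet} is used.
#' @param config a \linkS4class{TrainConfig}.
#' @return the fitted \linkS4class{TrainedModel} with per-epoch history.
#' @export
trainModel <- function(model, trainSet, valSet = NULL, config = trainConfig()) {
  stopifnot(is(model, "TrainedModel"), is(trainSet, "TrainingSet"),
            is(config, "TrainConfig"))
  cfg <- model@config
  d <- dim(trainSet@windows)
  if (d[2] != cfg@nSensors || d[3] != cfg@W || ncol(trainSet@targets) != cfg@nSources)
    .stopInvalidConfig("training set shapes do not match the network config")
  if (d[1] < 1L) .stopInvalidConfig("empty training set")

  # scalers estimated on the full training set
  inMean <- apply(trainSet@windows, 2, mean)
  inSd <- apply(trainSet@windows, 2, stats::sd)
  inSd[inSd == 0] <- 1
  tScale <- max(abs(trainSet@targets))
  if (tScale == 0) tScale <- 1

  X <- .standardizeWindows(trainSet@windows, inMean, inSd)
  Y <- trainSet@targets / tScale

  valX <- NULL; valY <- NULL
  idx <- seq_len(d[1])
  .withSeed(config@seed, {
    if (is.null(valSet) && config@valFraction > 0 && d[1] >= 10L) {
      nVal <- max(1L, floor(d[1] * config@valFraction))
      vi <- sample(idx, nVal)
      valX <- X[vi, , , drop = FALSE]; valY <- Y[vi, , drop = FALSE]
      idx <- setdiff(idx, vi)
    } else if (!is.null(valSet)) {
      valX <- .standardizeWindows(valSet@windows, inMean, inSd)
      valY <- valSet@targets / tScale
    }
    params <- model@params
    adam <- .adamInit(params)
    hist <- vector("list", config@epochs)
    for (ep in seq_len(config@epochs)) {
      ord <- sample(idx)
      nb <- ceiling(length(ord) / config@batchSize)
      epLoss <- 0; epN <- 0
      for (b in seq_len(nb)) {
        sel <- ord[((b - 1L) * config@batchSize + 1L):min(b * config@batchSize, length(ord))]
        fw <- .netForward(params, cfg, X[sel, , , drop = FALSE], train = TRUE)
        params <- fw$params  # batch-norm running stats
        res <- fw$pred - Y[sel, , drop = FALSE]
        loss <- mean(res^2)
        if (!is.finite(loss))
          stop("training aborted: non-finite loss at epoch ", ep, ", batch ", b,
               "; learning rate ", config@learningRate,
               ", input scale [", format(min(X)), ", ", format(max(X)),
               "], target scale ", format(tScale), call. = FALSE)
        epLoss <- epLoss + loss * length(sel); epN <- epN + length(sel)
        dPred <- 2 * res / length(res)
        grads <- .netBackward(params, cfg, dPred, fw$cache)
        st <- .adamStep(params, grads, adam, config@learningRate,
                        config@beta1, config@beta2, config@epsilon)
        params <- st$params; adam <- st$state
      }
      vLoss <- NA_real_
      if (!is.null(valX)) {
        pv <- .netForward(params, cfg, valX, train = FALSE)$pred
        vLoss <- mean((pv - valY)^2)
      }
      hist[[ep]] <- data.frame(epoch = ep, train = epLoss / epN, val = vLoss)
    }
    model@params <- params
    model@history <- do.call(rbind, hist)
  })
  model@inputMean <- inMean
  model@inputSd <- inSd
  model@targetScale <- tScale
  model
}

#' Predict source amplitudes from sensor windows
#'
#' Standardizes the window(s) with the model's stored constants, runs the
#' forward pass with batch-norm in inference mode (predictions are
#' batch-size invariant), and rescales the outputs back to amplitude units.
#'
#' @param model a fitted \linkS4class{TrainedModel}.
#' @param window an S x W matrix or an N x S x W array.
#' @return a D-vector (single window) or N x D matrix of amplitudes.
#' @export
predictWindow <- function(model, window) {
  stopifnot(is(model, "TrainedModel"))
  cfg <- model@config
  single <- length(dim(window)) == 2L
  if (single) window <- array(window, c(1L, dim(window)))
  d <- dim(window)
  if (d[2] != cfg@nSensors || d[3] != cfg@W)
    stop("input-contract: window must be ", cfg@nSensors, " x ", cfg@W,
         ", got ", d[2], " x ", d[3], call. = FALSE)
  X <- .standardizeWindows(window, model@inputMean, model@inputSd)
  pred <- .netForward(model@params, cfg, X, train = FALSE)$pred * model@targetScale
  if (single) drop(pred) else pred
}

#' Reconstruct full source time courses from a recording
#'
#' Slides the W-sample window over the recording; column c of the estimate
#' is the network prediction for the window centered at c. The (W-1)/2 edge
#' columns at each end cannot be centered and are zero-filled with
#' \code{validCols = FALSE}.
#'
#' @param model a fitted \linkS4class{TrainedModel}.
#' @param recording a \linkS4class{SensorRecording} with T >= W samples.
#' @return a \linkS4class{SourceActivity} estimate (D x T).
#' @export
reconstructTimeseries <- function(model, recording) {
  stopifnot(is(model, "TrainedModel"), is(recording, "SensorRecording"))
  cfg <- model@config
  M <- samples(recording)
  T <- ncol(M); W <- cfg@W; half <- (W - 1L) %/% 2L
  if (T < W) stop("input-contract: recording has ", T,
                  " samples but the window needs ", W, call. = FALSE)
  if (nrow(M) != cfg@nSensors)
    stop("input-contract: recording sensor count mismatch", call. = FALSE)
  centers <- seq.int(half + 1L, T - half)
  wins <- array(0, c(length(centers), cfg@nSensors, W))
  for (i in seq_along(centers))
    wins[i, , ] <- M[, (centers[i] - half):(centers[i] + half)]
  pred <- predictWindow(model, wins)  # N x D
  A <- matrix(0, cfg@nSources, T)
  A[, centers] <- t(pred)
  valid <- rep(FALSE, T); valid[centers] <- TRUE
  new("SourceActivity", amplitudes = A, validCols = valid)
}
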