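#' @include AllClasses.R
NULL

# vacuum permeability, H/m
MU0 <- 4 * pi * 1e-7

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Moore-Penrose pseudoinverse of a symmetric PSD matrix via eigen truncation
.pinvSym <- function(m, rtol = 1e-12) {
  e <- eigen(m, symmetric = TRUE)
  keep <- e$values > rtol * max(e$values, 0)
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  v <- e$vectors[, keep, drop = FALSE]
  v %*% (t(v) / e$values[keep])
}

# magnitude of the analytic signal (FFT-based Hilbert transform)
.envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

.stopInvalidGeometry <- function(msg) stop("invalid-geometry: ", msg, call. = FALSE)
.stopInvalidConfig <- function(msg) stop("invalid-config: ", msg, call. = FALSE)
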