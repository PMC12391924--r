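#' @include AllClasses.R utils.R
NULL

#' Default source-waveform parameter ranges
#'
#' Uniform sampling ranges for the Gaussian-damped sine parameters: Gaussian
#' center t0 in [0.05, 0.3] s, damping width omega in [0.04, 0.12] s, sine
#' frequency f0 in [8, 14] Hz (the alpha band), initial phase phi in
#' [0, 2*pi) rad.
#'
#' @return named list of \code{c(min, max)} pairs for t0, omega, f0, phi.
#' @export
defaultSignalRanges <- function() {
  list(t0 = c(0.05, 0.3), omega = c(0.04, 0.12),
       f0 = c(8, 14), phi = c(0, 2 * pi))
}

#' Draw source-waveform parameters uniformly from their ranges
#'
#' Each of t0, omega, f0, phi is drawn independently and uniformly on its
#' configured range (defaults: \code{\link{defaultSignalRanges}}). Uses the
#' global RNG; seed with \code{set.seed} for reproducibility.
#'
#' @param ranges named list of \code{c(min, max)} per parameter.
#' @return a \linkS4class{SignalParams}
#' @export
sampleSignalParams <- function(ranges = defaultSignalRanges()) {
  need <- c("t0", "omega", "f0", "phi")
  if (!all(need %in% names(ranges)))
    .stopInvalidConfig("ranges must name t0, omega, f0, phi")
  vals <- lapply(need, function(p) {
    r <- ranges[[p]]
    if (length(r) != 2L || r[1] > r[2])
      .stopInvalidConfig(sprintf("inverted or malformed range for %s", p))
    stats::runif(1, r[1], r[2])
  })
  names(vals) <- need
  new("SignalParams", t0 = vals$t0, omega = vals$omega,
      f0 = vals$f0, phi = vals$phi)
}

#' Evaluate a Gaussian-damped sinusoid
#'
#' \code{g(t) = sin(2*pi*f0*t + phi) * exp(-(t - t0)^2 / omega^2)} evaluated
#' pointwise on the time axis.
#'
#' @param params a \linkS4class{SignalParams}.
#' @param times strictly increasing sample times, seconds.
#' @return numeric vector of amplitudes, unit peak scale.
#' @examples
#' t <- makeTimeAxis()
#' g <- gaussianDampedSine(new("SignalParams", t0 = 0.2, omega = 0.08,
#'                             f0 = 10, phi = 0), t)
#' @export
gaussianDampedSine <- function(params, times) {
  stopifnot(is(params, "SignalParams"))
  if (params@omega == 0) stop("invalid-parameter: omega must be nonzero", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    .stopInvalidConfig("time axis must be strictly increasing")
  sin(2 * pi * params@f0 * times + params@phi) *
    exp(-(times - params@t0)^2 / params@omega^2)
}

#' Default trial time axis
#'
#' 0.4 s at 1 kHz sampling: 400 samples starting at t = 0.
#'
#' @param duration trial length, seconds.
#' @param fs sampling frequency, Hz.
#' @return numeric vector of sample times (length \code{duration * fs}).
#' @export
makeTimeAxis <- function(duration = 0.4, fs = 1000) {
  if (duration <= 0 || fs <= 0) .stopInvalidConfig("duration and fs must be positive")
  seq(0, by = 1 / fs, length.out = round(duration * fs))
}
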