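#' @include AllClasses.R forward.R
NULL

#' Simulate a noisy sensor recording
#'
#' Projects source activity through the leadfield (\code{M = L Q + N}) and
#' adds i.i.d. zero-mean white Gaussian noise per sensor and sample. The
#' noise variance is set so that the global power ratio
#' \code{10*log10(mean(clean^2) / sigma^2)}, averaged over all sensors and
#' samples, equals \code{snrDb}. \code{snrDb = Inf} produces a noiseless
#' recording.
#'
#' @param activity a \linkS4class{SourceActivity} (ground truth).
#' @param leadfield a \linkS4class{Leadfield} with matching source count.
#' @param snrDb requested sensor-space SNR in decibels (default Inf).
#' @param noiseSeed integer seed for the noise draw; drawn from the global
#'   RNG when NULL, and always recorded for replay.
#' @return a \linkS4class{SensorRecording}
#' @export
simulateRecording <- function(activity, leadfield, snrDb = Inf, noiseSeed = NULL) {
  stopifnot(is(activity, "SourceActivity"), is(leadfield, "Leadfield"))
  if (nrow(activity@amplitudes) != nSources(leadfield))
    .stopInvalidConfig("activity rows must match leadfield columns")
  clean <- gain(leadfield) %*% activity@amplitudes
  if (is.infinite(snrDb)) {
    return(new("SensorRecording", samples = clean, clean = clean,
               snrDb = Inf, noiseSeed = NA_integer_))
  }
  power <- mean(clean^2)
  if (power == 0)
    stop("undefined-SNR: all-zero clean signal with finite snrDb", call. = FALSE)
  if (is.null(noiseSeed)) noiseSeed <- sample.int(.Machine$integer.max, 1L)
  sigma <- sqrt(power / 10^(snrDb / 10))
  noise <- .withSeed(noiseSeed,
                     matrix(stats::rnorm(length(clean), sd = sigma),
                            nrow(clean), ncol(clean)))
  new("SensorRecording", samples = clean + noise, clean = clean,
      snrDb = snrDb, noiseSeed = as.integer(noiseSeed))
}

#' Realized SNR of a simulated recording
#'
#' Recomputes \code{10*log10(mean(clean^2) / mean(noise^2))} from the stored
#' clean part and the realized noise (samples - clean), for auditing the
#' noise calibration.
#'
#' @param recording a \linkS4class{SensorRecording}.
#' @return realized SNR in dB (Inf for noiseless recordings).
#' @export
realizedSnr <- function(recording) {
  stopifnot(is(recording, "SensorRecording"))
  noise <- recording@samples - recording@clean
  np <- mean(noise^2)
  if (np == 0) return(Inf)
  10 * log10(mean(recording@clean^2) / np)
}
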