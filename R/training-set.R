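#' @include AllClasses.R scenarios.R recording.R
NULL

#' Generate a windowed training set
#'
#' Draws \code{nExamples} independent trials. Each trial picks a scenario
#' kind (exactly \code{round(nExamples * focalFraction)} focal, the rest
#' extended), renders Gaussian-damped-sine activity on the trial time axis,
#' projects it through the leadfield, adds white sensor noise at an SNR
#' drawn uniformly from \code{snrRange}, picks a random valid window center,
#' and stores the S x W sensor window together with the ground-truth source
#' amplitude vector at the center sample.
#'
#' @param nExamples number of input/output pairs.
#' @param sourceSpace the \linkS4class{SourceSpace} targets are defined on.
#' @param leadfield the matching \linkS4class{Leadfield}.
#' @param focalFraction fraction of focal examples (default 0.5, an even
#'   focal/extended split).
#' @param W window length in samples (odd, default 21).
#' @param snrRange sensor SNR range in dB, drawn uniformly per example
#'   (default 0-30 dB).
#' @param times trial time axis (default 0.4 s at 1 kHz).
#' @param focalGroups,extendedGroups group-count choices sampled per example.
#' @param volumeRange extended-region volume bounds, cm^3.
#' @param signalRanges waveform parameter ranges.
#' @param seed integer seed; the whole set is reproducible from it.
#' @return a \linkS4class{TrainingSet}
#' @export
buildTrainingSet <- function(nExamples, sourceSpace, leadfield,
                             focalFraction = 0.5, W = 21L,
                             snrRange = c(0, 30), times = makeTimeAxis(),
                             focalGroups = 1L, extendedGroups = 1L,
                             volumeRange = c(14, 44),
                             signalRanges = defaultSignalRanges(),
                             seed = 1L) {
  W <- as.integer(W)
  T <- length(times)
  if (W %% 2L == 0L) .stopInvalidConfig("W must be odd")
  if (W > T) .stopInvalidConfig("W exceeds the trial length")
  if (focalFraction < 0 || focalFraction > 1)
    .stopInvalidConfig("focalFraction must be in [0, 1]")
  if (snrRange[1] > snrRange[2]) .stopInvalidConfig("inverted snrRange")
  S <- nSensors(leadfield); D <- nSources(sourceSpace)
  half <- (W - 1L) %/% 2L
  nFocal <- round(nExamples * focalFraction)
  windows <- array(0, c(nExamples, S, W))
  targets <- matrix(0, nExamples, D)
  centers <- integer(nExamples)
  snrs <- numeric(nExamples)
  kinds <- character(nExamples)
  .withSeed(seed, {
    kinds <- sample(c(rep("focal", nFocal), rep("extended", nExamples - nFocal)))
    for (i in seq_len(nExamples)) {
      if (kinds[i] == "focal") {
        ng <- if (length(focalGroups) == 1L) focalGroups else sample(focalGroups, 1L)
        kind <- if (ng == 1L) "single_focal" else "multi_focal"
        sc <- makeScenario(kind, sourceSpace, nGroups = ng, times = times,
                           signalRanges = signalRanges)
      } else {
        ng <- if (length(extendedGroups) == 1L) extendedGroups else sample(extendedGroups, 1L)
        sc <- makeScenario("extended", sourceSpace, nGroups = ng, times = times,
                           volumeRange = volumeRange, signalRanges = signalRanges)
      }
      act <- renderSourceActivity(sc)
      snrs[i] <- stats::runif(1, snrRange[1], snrRange[2])
      rec <- simulateRecording(act, leadfield, snrDb = snrs[i],
                               noiseSeed = sample.int(.Machine$integer.max, 1L))
      c0 <- sample(seq.int(half + 1L, T - half), 1L)
      centers[i] <- c0
      windows[i, , ] <- rec@samples[, (c0 - half):(c0 + half)]
      targets[i, ] <- act@amplitudes[, c0]
    }
  })
  new("TrainingSet", windows = windows, targets = targets,
      centers = centers, snrDb = snrs, kinds = kinds, seed = as.integer(seed))
}
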