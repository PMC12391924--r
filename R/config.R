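#' @include AllClasses.R signals.R
NULL

# Desk-scale defaults. The full-scale study design uses S = 127 sensors,
# a 5 mm forward / 15 mm inverse grid and 2e5 training examples; those
# values are accepted by the same fields but are far beyond interactive use.
.configDefaults <- function() list(
  geometry = list(
    nSensors = 32L,          # full scale: 127
    sensorRadius = 0.12,     # m
    capFraction = 0.6,
    sourceRadius = 0.07,     # m
    forwardSpacing = 0.025,  # m; full scale: 0.005
    inverseSpacing = 0.025,  # m; full scale: 0.015
    orientationSeed = 7L),
  signal = list(
    t0 = c(0.05, 0.3), omega = c(0.04, 0.12),
    f0 = c(8, 14), phi = c(0, 2 * pi),
    duration = 0.4, fs = 1000),
  dataset = list(
    nExamples = 5000L,       # full scale: 200000
    focalFraction = 0.5,
    snrRange = c(0, 30),
    W = 21L,
    volumeRange = c(14, 44)),
  network = list(
    convFeatures = c(16L, 32L, 64L, 128L),
    convKernels = NULL,
    fcLayers = 6L, fcWidth = 500L),
  training = list(
    epochs = 10L, learningRate = 1e-4, batchSize = 64L,
    valFraction = 0.1, seed = 1L),
  benchmark = list(
    methods = c("network", "lcmv", "eloreta", "mne", "rv"),
    kinds = "single_focal",
    testSnrDb = c(30, 10),
    nTestCases = 30L,
    thresholdFraction = 0.5,
    lcmvLoading = 0.05,
    seed = 1L))

.validateConfigSection <- function(given, defaults, section) {
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    .stopInvalidConfig(sprintf("unknown key(s) in section '%s': %s",
                               section, paste(unknown, collapse = ", ")))
  out <- defaults
  for (k in names(given)) {
    if (is.null(given[[k]])) out[k] <- list(NULL) else out[[k]] <- given[[k]]
  }
  out
}

#' Build a validated run configuration
#'
#' Starts from desk-scale defaults and overrides any subset of keys;
#' unknown keys are rejected by name. Sections: \code{geometry} (sensor
#' count/radius/cap, source radius, forward and inverse lattice spacing),
#' \code{signal} (waveform parameter ranges, trial duration, sampling
#' frequency), \code{dataset} (example count, focal fraction, SNR range,
#' window length, extended-region volume bounds), \code{network},
#' \code{training}, and \code{benchmark} (methods, scenario kinds, test
#' SNRs, case count, threshold, seed).
#'
#' @param geometry,signal,dataset,network,training,benchmark named lists of
#'   overrides.
#' @return a validated \linkS4class{RunConfig}
#' @examples
#' cfg <- runConfig(dataset = list(nExamples = 200L))
#' @export
runConfig <- function(geometry = list(), signal = list(), dataset = list(),
                      network = list(), training = list(), benchmark = list()) {
  def <- .configDefaults()
  cfg <- new("RunConfig",
    geometry = .validateConfigSection(geometry, def$geometry, "geometry"),
    signal = .validateConfigSection(signal, def$signal, "signal"),
    dataset = .validateConfigSection(dataset, def$dataset, "dataset"),
    network = .validateConfigSection(network, def$network, "network"),
    training = .validateConfigSection(training, def$training, "training"),
    benchmark = .validateConfigSection(benchmark, def$benchmark, "benchmark"))
  g <- cfg@geometry
  for (k in c("nSensors", "sensorRadius", "capFraction", "sourceRadius",
              "forwardSpacing", "inverseSpacing"))
    if (g[[k]] <= 0) .stopInvalidConfig(paste0("geometry$", k, " must be positive"))
  if (g$sensorRadius <= g$sourceRadius)
    .stopInvalidConfig("sensorRadius must exceed sourceRadius")
  s <- cfg@signal
  for (k in c("t0", "omega", "f0", "phi"))
    if (length(s[[k]]) != 2L || s[[k]][1] > s[[k]][2])
      .stopInvalidConfig(paste0("signal$", k, " must be an ordered range"))
  if (s$duration <= 0 || s$fs <= 0)
    .stopInvalidConfig("signal duration and fs must be positive")
  d <- cfg@dataset
  if (d$snrRange[1] > d$snrRange[2])
    .stopInvalidConfig("dataset$snrRange is inverted")
  if (d$W %% 2L == 0L) .stopInvalidConfig("dataset$W must be odd")
  if (d$focalFraction < 0 || d$focalFraction > 1)
    .stopInvalidConfig("dataset$focalFraction must be in [0, 1]")
  b <- cfg@benchmark
  bad <- setdiff(b$methods, c("network", "lcmv", "eloreta", "mne", "rv"))
  if (length(bad))
    .stopInvalidConfig(paste("unknown benchmark method(s):",
                             paste(bad, collapse = ", ")))
  bad <- setdiff(b$kinds, c("single_focal", "multi_focal", "extended"))
  if (length(bad))
    .stopInvalidConfig(paste("unknown scenario kind(s):",
                             paste(bad, collapse = ", ")))
  cfg
}

.configAsList <- function(config)
  list(geometry = config@geometry, signal = config@signal,
       dataset = config@dataset, network = config@network,
       training = config@training, benchmark = config@benchmark)

#' Load / save a run configuration as YAML
#'
#' An empty file yields the all-defaults configuration; any provided key
#' overrides its default, and unknown keys are rejected by name. The fully
#' resolved configuration round-trips through \code{saveRunConfig}.
#'
#' @param path YAML file path.
#' @return a validated \linkS4class{RunConfig}
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.configDefaults()))
  if (length(unknown))
    .stopInvalidConfig(paste("unknown section(s):", paste(unknown, collapse = ", ")))
  do.call(runConfig, raw)
}

#' @rdname loadRunConfig
#' @param config a \linkS4class{RunConfig}.
#' @export
saveRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  yaml::write_yaml(.configAsList(config), path, precision = 15L)
  invisible(path)
}
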