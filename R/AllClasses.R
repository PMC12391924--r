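#' @import methods
NULL

.approxZero <- function(x, tol) all(abs(x) < tol)

#' SensorArray: radial magnetometer helmet geometry
#'
#' Positions and sensing orientations of S magnetometers, head-centered, in
#' meters. Under the spherically symmetric conductor model the sensors are
#' assumed to measure the radial component of the magnetic field, so every
#' orientation must be the unit vector parallel to its position.
#'
#' @slot positions S x 3 numeric matrix, meters.
#' @slot orientations S x 3 numeric matrix of unit radial vectors.
#' @exportClass SensorArray
setClass("SensorArray",
  representation(positions = "matrix", orientations = "matrix"),
  validity = function(object) {
    p <- object@positions; o <- object@orientations
    if (ncol(p) != 3L || ncol(o) != 3L) return("positions/orientations must have 3 columns")
    if (nrow(p) != nrow(o)) return("positions and orientations differ in row count")
    if (nrow(p) < 1L) return("at least one sensor required")
    if (!all(is.finite(p)) || !all(is.finite(o))) return("non-finite geometry")
    nrm <- sqrt(rowSums(o^2))
    if (!.approxZero(nrm - 1, 1e-12)) return("orientations must have unit norm (1e-12)")
    rad <- sqrt(rowSums(p^2))
    if (any(rad == 0)) return("sensor at the origin is not a radial geometry")
    # radial sensing: orientation parallel to position
    cosang <- rowSums(o * p) / rad
    if (!.approxZero(abs(cosang) - 1, 1e-10)) return("orientations must be radial (parallel to positions)")
    TRUE
  })

#' SourceSpace: cubic dipole lattice inside a spherical conductor
#'
#' A regular cubic lattice of candidate current dipoles strictly inside the
#' conductor sphere. Each dipole carries a fixed unit tangential orientation
#' (radial dipoles are magnetically silent in the spherical model, so only
#' tangential moments are represented). If the exact origin falls inside the
#' sphere it is kept with a fixed +x orientation and flagged via
#' \code{originIndex}.
#'
#' @slot positions D x 3 numeric matrix, meters.
#' @slot orientations D x 3 numeric matrix of unit tangential vectors.
#' @slot spacing lattice step, meters.
#' @slot radius conductor (source sphere) radius, meters.
#' @slot originIndex row index of the origin point, or 0L if absent.
#' @exportClass SourceSpace
setClass("SourceSpace",
  representation(positions = "matrix", orientations = "matrix",
                 spacing = "numeric", radius = "numeric",
                 originIndex = "integer"),
  validity = function(object) {
    p <- object@positions; o <- object@orientations; h <- object@spacing
    if (ncol(p) != 3L || nrow(p) < 1L) return("positions must be a D x 3 matrix")
    if (!identical(dim(p), dim(o))) return("positions/orientations dimension mismatch")
    if (length(h) != 1L || h <= 0) return("spacing must be a positive scalar")
    rad <- sqrt(rowSums(p^2))
    if (any(rad >= object@radius)) return("all sources must lie strictly inside the conductor sphere")
    # regular cubic lattice: coordinates are integer multiples of spacing
    k <- p / h
    if (!.approxZero(k - round(k), 1e-8)) return("positions are not on the declared cubic lattice")
    nrm <- sqrt(rowSums(o^2))
    if (!.approxZero(nrm - 1, 1e-12)) return("orientations must have unit norm")
    tang <- rowSums(o * p)  # zero for tangential dipoles (origin exempt)
    chk <- seq_len(nrow(p)) != object@originIndex
    if (!.approxZero(tang[chk], 1e-10)) return("orientations must be tangential (1e-10)")
    TRUE
  })

#' Leadfield: forward gain matrix of the spherical head model
#'
#' S x D matrix mapping unit dipole amplitudes (A*m) to radial magnetometer
#' readings (tesla). Column d holds the field of dipole d at every sensor;
#' dipole orientations are folded in, so the forward model is
#' \code{M = gain \%*\% Q + N}.
#'
#' @slot gain S x D numeric matrix, tesla per (A*m).
#' @slot sensors the \linkS4class{SensorArray} used.
#' @slot sources the \linkS4class{SourceSpace} used.
#' @exportClass Leadfield
setClass("Leadfield",
  representation(gain = "matrix", sensors = "SensorArray", sources = "SourceSpace"),
  validity = function(object) {
    if (nrow(object@gain) != nrow(object@sensors@positions))
      return("gain rows must equal sensor count")
    if (ncol(object@gain) != nrow(object@sources@positions))
      return("gain columns must equal source count")
    if (!all(is.finite(object@gain))) return("gain entries must be finite")
    TRUE
  })

#' SignalParams: parameters of a Gaussian-damped sinusoid
#'
#' One source waveform \code{g(t) = sin(2*pi*f0*t + phi) *
#' exp(-(t - t0)^2 / omega^2)}: a sine at frequency \code{f0} (Hz) with
#' initial phase \code{phi} (rad), damped by a Gaussian envelope centered at
#' \code{t0} (s) with width \code{omega} (s).
#'
#' @slot t0 Gaussian center, seconds.
#' @slot omega Gaussian damping width, seconds (> 0).
#' @slot f0 sine frequency, Hz.
#' @slot phi initial phase, radians.
#' @exportClass SignalParams
setClass("SignalParams",
  representation(t0 = "numeric", omega = "numeric", f0 = "numeric", phi = "numeric"),
  validity = function(object) {
    for (s in c("t0", "omega", "f0", "phi"))
      if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
        return(sprintf("%s must be a finite scalar", s))
    if (object@omega <= 0) return("omega must be strictly positive")
    TRUE
  })

#' Scenario: a ground-truth activation pattern
#'
#' Which dipoles are active and with what waveform. Focal groups are single
#' dipoles with individual waveforms; extended groups are lattice-connected
#' voxel sets sharing one waveform.
#'
#' @slot kind one of \code{"single_focal"}, \code{"multi_focal"},
#'   \code{"extended"}.
#' @slot groups list; each element is \code{list(indices = <integer>,
#'   params = <SignalParams>)}.
#' @slot nSources D, the size of the source space the indices refer to.
#' @slot times sample times, seconds (length T).
#' @slot fs sampling frequency, Hz.
#' @exportClass Scenario
setClass("Scenario",
  representation(kind = "character", groups = "list", nSources = "integer",
                 times = "numeric", fs = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("single_focal", "multi_focal", "extended"))
      return("unknown scenario kind")
    idx <- unlist(lapply(object@groups, `[[`, "indices"))
    if (anyDuplicated(idx)) return("active groups must be disjoint")
    if (length(idx) && (min(idx) < 1L || max(idx) > object@nSources))
      return("active indices out of range")
    if (object@kind %in% c("single_focal", "multi_focal")) {
      if (!all(vapply(object@groups, function(g) length(g$indices) == 1L, logical(1))))
        return("focal groups must be singletons")
    }
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
      return("time axis must be strictly increasing")
    TRUE
  })

#' SourceActivity: dipole amplitude time courses
#'
#' D x T matrix of dipole amplitudes (A*m), either ground truth or a solver
#' estimate. \code{validCols} marks time samples actually estimated; edge
#' columns that a windowed estimator cannot reach are zero-filled and flagged
#' FALSE.
#'
#' @slot amplitudes D x T numeric matrix.
#' @slot validCols logical vector of length T.
#' @exportClass SourceActivity
setClass("SourceActivity",
  representation(amplitudes = "matrix", validCols = "logical"),
  validity = function(object) {
    if (length(object@validCols) != ncol(object@amplitudes))
      return("validCols length must equal the number of time samples")
    if (!all(is.finite(object@amplitudes))) return("amplitudes must be finite")
    TRUE
  })

#' SensorRecording: measured (simulated) sensor data
#'
#' S x T matrix of radial magnetometer samples in tesla, the clean forward
#' projection plus white Gaussian sensor noise at the annotated SNR. The
#' clean part is retained so realized SNR can be audited.
#'
#' @slot samples S x T numeric matrix, tesla (clean + noise).
#' @slot clean S x T numeric matrix, noiseless forward projection.
#' @slot snrDb requested signal-to-noise ratio in dB (\code{Inf} = noiseless).
#' @slot noiseSeed integer seed used for the noise draw (NA if noiseless).
#' @exportClass SensorRecording
setClass("SensorRecording",
  representation(samples = "matrix", clean = "matrix", snrDb = "numeric",
                 noiseSeed = "integer"),
  validity = function(object) {
    if (!identical(dim(object@samples), dim(object@clean)))
      return("samples/clean dimension mismatch")
    if (!all(is.finite(object@samples))) return("samples must be finite")
    TRUE
  })

#' TrainingSet: windowed examples for the network
#'
#' N sensor windows (S x W each) paired with the ground-truth source
#' amplitude vector at each window's center sample.
#'
#' @slot windows N x S x W numeric array.
#' @slot targets N x D numeric matrix.
#' @slot centers integer vector of center sample indices (1-based).
#' @slot snrDb numeric vector of per-example sensor SNRs (dB).
#' @slot kinds character vector of scenario kinds per example.
#' @slot seed integer seed the set was generated from.
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(windows = "array", targets = "matrix", centers = "integer",
                 snrDb = "numeric", kinds = "character", seed = "integer"),
  validity = function(object) {
    d <- dim(object@windows)
    if (length(d) != 3L) return("windows must be an N x S x W array")
    if (d[1] != nrow(object@targets)) return("windows/targets count mismatch")
    if (d[3] %% 2L == 0L) return("window length W must be odd")
    if (length(object@centers) != d[1]) return("centers length mismatch")
    TRUE
  })

#' NetworkConfig: architecture of the windowed inverse network
#'
#' Four (by default) 1-D temporal convolutions shared across sensors collapse
#' the W-sample window to a single time point with 128 features per sensor;
#' the flattened S x 128 map feeds 6 fully-connected ReLU layers of width 500
#' and a final linear layer with one output per dipole.
#'
#' @slot W window length in samples (odd).
#' @slot convFeatures feature counts per conv layer (last one is the
#'   flattened per-sensor feature depth).
#' @slot convKernels odd kernel lengths per conv layer; must consume W down
#'   to temporal extent 1.
#' @slot fcLayers number of hidden fully-connected layers.
#' @slot fcWidth nodes per hidden fully-connected layer.
#' @slot nSensors S.
#' @slot nSources D.
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(W = "integer", convFeatures = "integer", convKernels = "integer",
                 fcLayers = "integer", fcWidth = "integer",
                 nSensors = "integer", nSources = "integer"),
  validity = function(object) {
    if (object@W %% 2L == 0L) return("W must be odd")
    if (length(object@convFeatures) != length(object@convKernels))
      return("convFeatures and convKernels must have equal length")
    ext <- object@W
    exts <- integer(0)
    for (k in object@convKernels) { ext <- ext - k + 1L; exts <- c(exts, ext) }
    if (any(exts < 1L) || exts[length(exts)] != 1L)
      return(sprintf(
        "conv kernel schedule must reduce W=%d to temporal extent 1; achieved extents: %s",
        object@W, paste(exts, collapse = " -> ")))
    if (object@fcLayers < 1L || object@fcWidth < 1L) return("invalid FC block")
    TRUE
  })

#' TrainConfig: optimization settings
#'
#' Adam with mean-squared-error loss on minibatches; fully deterministic
#' given \code{seed}.
#'
#' @slot learningRate Adam step size (default 1e-4).
#' @slot batchSize minibatch size (default 64).
#' @slot epochs passes over the training set.
#' @slot seed integer RNG seed for init and shuffling.
#' @slot valFraction fraction held out for validation (0 disables).
#' @slot beta1,beta2,epsilon Adam moment decay / stabilizer constants.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", seed = "integer", valFraction = "numeric",
                 beta1 = "numeric", beta2 = "numeric", epsilon = "numeric"),
  validity = function(object) {
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@valFraction < 0 || object@valFraction >= 1)
      return("valFraction must be in [0, 1)")
    TRUE
  })

#' TrainedModel: fitted network plus its preprocessing constants
#'
#' Opaque parameter store together with the architecture, the per-sensor
#' input standardization constants and global target scale estimated on the
#' training set, and the per-epoch loss history. Scalers travel with the
#' model and are applied consistently at inference.
#'
#' @slot params list of layer parameter matrices.
#' @slot config the \linkS4class{NetworkConfig}.
#' @slot inputMean,inputSd per-sensor standardization constants.
#' @slot targetScale global amplitude scale applied to targets.
#' @slot history data.frame with per-epoch train (and validation) MSE.
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(params = "list", config = "NetworkConfig",
                 inputMean = "numeric", inputSd = "numeric",
                 targetScale = "numeric", history = "data.frame"))

#' Covariance: sensor covariance with diagonal loading
#'
#' @slot matrix S x S symmetric positive semi-definite matrix, tesla^2.
#' @slot loadingFraction diagonal loading applied, as a fraction of the mean
#'   sensor variance (trace/S).
#' @exportClass Covariance
setClass("Covariance",
  representation(matrix = "matrix", loadingFraction = "numeric"),
  validity = function(object) {
    m <- object@matrix
    if (nrow(m) != ncol(m)) return("covariance must be square")
    if (max(abs(m - t(m))) > 1e-12 * max(1, max(abs(m))))
      return("covariance must be symmetric (1e-12)")
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1)) return("covariance must be positive semi-definite")
    TRUE
  })

#' InverseSolution: output of an inverse solver
#'
#' Estimated D x T amplitudes (all solvers), plus per-dipole scan scores for
#' the residual-variance method (fraction of unexplained sensor power, in
#' [0, 1]).
#'
#' @slot amplitudes D x T numeric matrix of estimated dipole amplitudes.
#' @slot scores numeric vector of length D (RV scan) or length 0.
#' @slot method solver tag ("lcmv", "mne", "eloreta", "rv", "network").
#' @slot hyperparameters list of solver settings actually used.
#' @slot info list of diagnostics (convergence flag, iterations, ...).
#' @exportClass InverseSolution
setClass("InverseSolution",
  representation(amplitudes = "matrix", scores = "numeric", method = "character",
                 hyperparameters = "list", info = "list"),
  validity = function(object) {
    if (length(object@scores) &&
        (min(object@scores) < 0 || max(object@scores) > 1))
      return("scan scores must lie in [0, 1]")
    TRUE
  })

#' ActiveSet: dipoles above the energy threshold
#'
#' Dipoles whose time-integrated energy exceeds \code{thresholdFraction}
#' (default 0.5) of the maximum dipole energy — the activity criterion used
#' by all localization metrics.
#'
#' @slot indices integer vector of active dipole indices (1-based).
#' @slot energies numeric vector of per-dipole energies (all dipoles).
#' @slot thresholdFraction the fraction of the maximum used.
#' @exportClass ActiveSet
setClass("ActiveSet",
  representation(indices = "integer", energies = "numeric",
                 thresholdFraction = "numeric"),
  validity = function(object) {
    if (length(object@energies)) {
      thr <- object@thresholdFraction * max(object@energies)
      inA <- seq_along(object@energies) %in% object@indices
      if (any(object@energies[inA] < thr) || any(object@energies[!inA] > thr))
        return("membership inconsistent with the energy threshold")
    }
    TRUE
  })

#' RunConfig: full experiment configuration
#'
#' Nested sections controlling geometry, the signal model, dataset
#' generation, the network and its training, and the benchmark design. Use
#' \code{\link{runConfig}} / \code{\link{loadRunConfig}} to construct with
#' validated defaults.
#'
#' @slot geometry,signal,dataset,network,training,benchmark named lists.
#' @exportClass RunConfig
setClass("RunConfig",
  representation(geometry = "list", signal = "list", dataset = "list",
                 network = "list", training = "list", benchmark = "list"))
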