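#' @include AllClasses.R
NULL

#' Number of sensors
#' @param x a SensorArray, Leadfield, or SensorRecording
#' @return integer S
#' @export
setGeneric("nSensors", function(x) standardGeneric("nSensors"))

#' Number of source dipoles
#' @param x a SourceSpace, Leadfield, or SourceActivity
#' @return integer D
#' @export
setGeneric("nSources", function(x) standardGeneric("nSources"))

#' Gain matrix of a leadfield
#' @param x a Leadfield
#' @return S x D numeric matrix, tesla per (A*m)
#' @export
setGeneric("gain", function(x) standardGeneric("gain"))

#' Dipole amplitude matrix
#' @param x a SourceActivity or InverseSolution
#' @return D x T numeric matrix
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' Sensor sample matrix
#' @param x a SensorRecording
#' @return S x T numeric matrix, tesla
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' Voxel volume of a cubic source lattice
#' @param x a SourceSpace
#' @return volume of one lattice voxel in cm^3 (spacing^3)
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' Active dipole indices
#' @param x an ActiveSet
#' @return integer vector of 1-based dipole indices
#' @export
setGeneric("activeIndices", function(x) standardGeneric("activeIndices"))

#' @rdname nSensors
#' @export
setMethod("nSensors", "SensorArray", function(x) nrow(x@positions))
#' @rdname nSensors
#' @export
setMethod("nSensors", "Leadfield", function(x) nrow(x@gain))
#' @rdname nSensors
#' @export
setMethod("nSensors", "SensorRecording", function(x) nrow(x@samples))

#' @rdname nSources
#' @export
setMethod("nSources", "SourceSpace", function(x) nrow(x@positions))
#' @rdname nSources
#' @export
setMethod("nSources", "Leadfield", function(x) ncol(x@gain))
#' @rdname nSources
#' @export
setMethod("nSources", "SourceActivity", function(x) nrow(x@amplitudes))

#' @rdname gain
#' @export
setMethod("gain", "Leadfield", function(x) x@gain)

#' @rdname amplitudes
#' @export
setMethod("amplitudes", "SourceActivity", function(x) x@amplitudes)
#' @rdname amplitudes
#' @export
setMethod("amplitudes", "InverseSolution", function(x) x@amplitudes)

#' @rdname samples
#' @export
setMethod("samples", "SensorRecording", function(x) x@samples)

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "SourceSpace", function(x) (x@spacing * 100)^3)

#' @rdname activeIndices
#' @export
setMethod("activeIndices", "ActiveSet", function(x) x@indices)

#' Sensor positions
#' @param x a SensorArray or Leadfield
#' @return S x 3 matrix, meters
#' @export
setGeneric("sensorPositions", function(x) standardGeneric("sensorPositions"))
#' @rdname sensorPositions
#' @export
setMethod("sensorPositions", "SensorArray", function(x) x@positions)
#' @rdname sensorPositions
#' @export
setMethod("sensorPositions", "Leadfield", function(x) x@sensors@positions)

#' Source dipole positions
#' @param x a SourceSpace or Leadfield
#' @return D x 3 matrix, meters
#' @export
setGeneric("sourcePositions", function(x) standardGeneric("sourcePositions"))
#' @rdname sourcePositions
#' @export
setMethod("sourcePositions", "SourceSpace", function(x) x@positions)
#' @rdname sourcePositions
#' @export
setMethod("sourcePositions", "Leadfield", function(x) x@sources@positions)

setMethod("show", "SensorArray", function(object) {
  cat(sprintf("SensorArray: %d radial magnetometers, radius %.3g m\n",
              nSensors(object), mean(sqrt(rowSums(object@positions^2)))))
})

setMethod("show", "SourceSpace", function(object) {
  cat(sprintf("SourceSpace: %d dipoles, %.1f mm cubic lattice inside r = %.3g m (voxel %.3g cm^3)\n",
              nSources(object), object@spacing * 1000, object@radius,
              voxelVolume(object)))
})

setMethod("show", "Leadfield", function(object) {
  cat(sprintf("Leadfield: %d sensors x %d dipoles; |gain| range [%.3g, %.3g] T/(A*m)\n",
              nSensors(object), nSources(object),
              min(abs(object@gain)), max(abs(object@gain))))
})

setMethod("show", "Scenario", function(object) {
  sz <- vapply(object@groups, function(g) length(g$indices), integer(1))
  cat(sprintf("Scenario '%s': %d active group(s) of size %s; T = %d @ %g Hz\n",
              object@kind, length(object@groups), paste(sz, collapse = ","),
              length(object@times), object@fs))
})

setMethod("show", "SourceActivity", function(object) {
  cat(sprintf("SourceActivity: %d dipoles x %d samples (%d valid), %d nonzero row(s)\n",
              nrow(object@amplitudes), ncol(object@amplitudes),
              sum(object@validCols), sum(rowSums(abs(object@amplitudes)) > 0)))
})

setMethod("show", "SensorRecording", function(object) {
  cat(sprintf("SensorRecording: %d sensors x %d samples, SNR %s dB\n",
              nrow(object@samples), ncol(object@samples),
              format(object@snrDb)))
})

setMethod("show", "TrainingSet", function(object) {
  d <- dim(object@windows)
  cat(sprintf("TrainingSet: %d examples, window %d sensors x %d samples -> %d targets\n",
              d[1], d[2], d[3], ncol(object@targets)))
})

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf(
    "NetworkConfig: S=%d, D=%d, W=%d | conv %s (kernels %s) | FC %d x %d\n",
    object@nSensors, object@nSources, object@W,
    paste(object@convFeatures, collapse = "-"),
    paste(object@convKernels, collapse = "-"),
    object@fcLayers, object@fcWidth))
})

setMethod("show", "TrainedModel", function(object) {
  np <- sum(vapply(unlist(object@params, recursive = FALSE), length, integer(1)))
  cat(sprintf("TrainedModel: %d parameters, %d training epoch(s), final train MSE %.4g\n",
              np, nrow(object@history),
              if (nrow(object@history)) utils::tail(object@history$train, 1) else NA))
})

setMethod("show", "InverseSolution", function(object) {
  cat(sprintf("InverseSolution [%s]: %d dipoles x %d samples\n",
              object@method, nrow(object@amplitudes), ncol(object@amplitudes)))
})

setMethod("show", "ActiveSet", function(object) {
  cat(sprintf("ActiveSet: %d of %d dipoles above %.0f%% of max energy\n",
              length(object@indices), length(object@energies),
              100 * object@thresholdFraction))
})
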