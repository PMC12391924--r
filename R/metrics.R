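#' @include AllClasses.R utils.R
NULL

#' Threshold dipole energies into an active set
#'
#' A dipole counts as active when its time-integrated energy (sum of squared
#' amplitude over the valid time region) is higher than
#' \code{thresholdFraction} of the maximum dipole energy — the 50%-of-max
#' criterion used by all localization metrics.
#'
#' @param activity a \linkS4class{SourceActivity} (truth or estimate) or a
#'   D x T numeric matrix.
#' @param thresholdFraction fraction of the maximum energy (default 0.5).
#' @return an \linkS4class{ActiveSet}; empty (with a warning) for all-zero
#'   activity.
#' @export
activeSet <- function(activity, thresholdFraction = 0.5) {
  if (is(activity, "SourceActivity")) {
    A <- activity@amplitudes[, activity@validCols, drop = FALSE]
  } else A <- as.matrix(activity)
  if (!length(A)) .stopInvalidConfig("empty activity")
  energies <- rowSums(A^2)
  if (max(energies) == 0) {
    warning("all-zero activity: empty active set")
    return(new("ActiveSet", indices = integer(0), energies = energies,
               thresholdFraction = thresholdFraction))
  }
  idx <- which(energies > thresholdFraction * max(energies))
  new("ActiveSet", indices = as.integer(idx), energies = energies,
      thresholdFraction = thresholdFraction)
}

#' Distance of localization error (DLE)
#'
#' Mean over the true active sources of the minimum Euclidean distance to
#' any estimated active source, in millimeters. Positions are compared in
#' physical space, so differing forward and inverse grids are handled
#' without snapping. Not symmetric: the average runs over the first
#' argument. An empty estimated set yields \code{Inf} with attribute
#' \code{empty = TRUE}.
#'
#' @param truePositions K x 3 matrix of true source positions, meters.
#' @param estPositions H x 3 matrix of estimated source positions, meters.
#' @return DLE in mm.
#' @export
dle <- function(truePositions, estPositions) {
  truePositions <- rbind(truePositions)
  if (!nrow(truePositions)) .stopInvalidConfig("empty true source set")
  if (is.null(estPositions) || !nrow(rbind(estPositions))) {
    out <- Inf
    attr(out, "empty") <- TRUE
    return(out)
  }
  estPositions <- rbind(estPositions)
  d <- vapply(seq_len(nrow(truePositions)), function(k) {
    diff <- sweep(estPositions, 2, truePositions[k, ], "-")
    sqrt(min(rowSums(diff^2)))
  }, numeric(1))
  mean(d) * 1000
}

#' Active volume (AV)
#'
#' Total volume of the active dipoles: \code{|indices| * voxelVolume}, in
#' cm^3. A measure of localization spread; additive over disjoint sets.
#'
#' @param aset an \linkS4class{ActiveSet}.
#' @param sourceSpace the \linkS4class{SourceSpace} the indices refer to.
#' @return volume in cm^3.
#' @export
activeVolume <- function(aset, sourceSpace) {
  stopifnot(is(aset, "ActiveSet"), is(sourceSpace, "SourceSpace"))
  if (length(aset@indices) &&
      max(aset@indices) > nSources(sourceSpace))
    .stopInvalidConfig("active indices exceed the source space")
  length(aset@indices) * voxelVolume(sourceSpace)
}

#' Normalized root-mean-square envelope error (NRMSE)
#'
#' Both traces are normalized by the square root of their energy, the
#' envelope of each normalized trace is taken as the magnitude of its
#' analytic signal, and the root-mean-square difference of the two
#' envelopes is returned. Scale-invariant in either argument.
#'
#' @param trueTrace,estTrace amplitude vectors over the same (valid) time
#'   region.
#' @return dimensionless error >= 0.
#' @export
nrmse <- function(trueTrace, estTrace) {
  if (length(trueTrace) != length(estTrace))
    .stopInvalidConfig("traces must have equal length")
  eT <- sum(trueTrace^2); eE <- sum(estTrace^2)
  if (eT == 0 || eE == 0)
    stop("undefined-metric: zero-energy trace", call. = FALSE)
  envT <- .envelope(trueTrace / sqrt(eT))
  envE <- .envelope(estTrace / sqrt(eE))
  sqrt(mean((envT - envE)^2))
}

#' Intersection over union of active sets
#'
#' \code{100 * |intersection| / |union|} of the true and estimated active
#' dipole index sets over a common source space; 0 when the union is empty.
#' Symmetric; 100 iff the sets are equal and non-empty.
#'
#' @param trueSet,estSet \linkS4class{ActiveSet}s over the same source
#'   space.
#' @return IoU in percent, in [0, 100].
#' @export
iou <- function(trueSet, estSet) {
  stopifnot(is(trueSet, "ActiveSet"), is(estSet, "ActiveSet"))
  if (length(trueSet@energies) != length(estSet@energies))
    stop("input-contract: active sets refer to different source spaces",
         call. = FALSE)
  u <- union(trueSet@indices, estSet@indices)
  if (!length(u)) return(0)
  100 * length(intersect(trueSet@indices, estSet@indices)) / length(u)
}

#' Split single-focal test cases into deep and cortical subsets
#'
#' The deep point is the dipole with the greatest mean distance from all
#' sensors. Cases are ranked by the distance of their active source to the
#' deep point; the closest \code{fraction} form the deep subset, the rest
#' the cortical subset.
#'
#' @param caseIndices integer vector: the active dipole index of each
#'   single-focal test case.
#' @param sourceSpace the \linkS4class{SourceSpace}.
#' @param sensors the \linkS4class{SensorArray}.
#' @param fraction fraction of cases assigned to the deep subset
#'   (default 0.5).
#' @return list with elements \code{deep} and \code{cortical} (positions in
#'   \code{caseIndices}), plus \code{deepPoint} (dipole index) and
#'   \code{distances}.
#' @export
depthSplit <- function(caseIndices, sourceSpace, sensors, fraction = 0.5) {
  stopifnot(is(sourceSpace, "SourceSpace"), is(sensors, "SensorArray"))
  caseIndices <- as.integer(caseIndices)
  if (any(caseIndices < 1L | caseIndices > nSources(sourceSpace)))
    stop("input-contract: case indices outside the source space", call. = FALSE)
  P <- sourceSpace@positions; Spos <- sensors@positions
  meanDist <- vapply(seq_len(nrow(P)), function(d) {
    mean(sqrt(rowSums(sweep(Spos, 2, P[d, ], "-")^2)))
  }, numeric(1))
  deepPoint <- which.max(meanDist)
  dist2deep <- sqrt(rowSums(sweep(P[caseIndices, , drop = FALSE], 2,
                                  P[deepPoint, ], "-")^2))
  ord <- order(dist2deep)
  nDeep <- round(length(caseIndices) * fraction)
  list(deep = sort(ord[seq_len(nDeep)]),
       cortical = sort(ord[setdiff(seq_along(ord), seq_len(nDeep))]),
       deepPoint = deepPoint, distances = dist2deep)
}
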