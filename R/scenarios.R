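#' @include AllClasses.R signals.R forward.R
NULL

# integer lattice coordinates and a fast key -> index lookup
.latticeIndex <- function(sourceSpace) {
  k <- round(sourceSpace@positions / sourceSpace@spacing)
  span <- max(abs(k)) + 2L
  key <- (k[, 1] + span) + (2L * span + 1L) * ((k[, 2] + span) +
         (2L * span + 1L) * (k[, 3] + span))
  lookup <- new.env(hash = TRUE, size = nrow(k))
  for (d in seq_len(nrow(k))) assign(as.character(key[d]), d, envir = lookup)
  list(coords = k, span = span, lookup = lookup)
}

.latticeNeighbors <- function(d, lat) {
  off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  kk <- sweep(off, 2, lat$coords[d, ], "+")
  key <- (kk[, 1] + lat$span) + (2L * lat$span + 1L) * ((kk[, 2] + lat$span) +
         (2L * lat$span + 1L) * (kk[, 3] + lat$span))
  out <- integer(0)
  for (x in as.character(key)) {
    v <- get0(x, envir = lat$lookup, inherits = FALSE)
    if (!is.null(v)) out <- c(out, v)
  }
  out
}

# grow a connected region of nVox voxels by uniform random frontier accretion
.growRegion <- function(seedVoxel, nVox, lat, exclude = integer(0)) {
  region <- seedVoxel
  frontier <- setdiff(.latticeNeighbors(seedVoxel, lat), exclude)
  while (length(region) < nVox) {
    frontier <- setdiff(frontier, region)
    if (!length(frontier)) return(NULL)
    pick <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    region <- c(region, pick)
    frontier <- union(frontier, setdiff(.latticeNeighbors(pick, lat), exclude))
  }
  region
}

#' Draw a ground-truth activation scenario
#'
#' Focal scenarios activate \code{nGroups} distinct dipoles, each with its
#' own waveform parameters. Extended scenarios grow \code{nGroups} disjoint
#' lattice-connected regions (6-neighborhood) by uniform random frontier
#' accretion from a random seed voxel, until a volume drawn from
#' \code{volumeRange} is reached; all voxels of a region share one waveform.
#' Region sizes are drawn as integer voxel counts whose realized volume is
#' guaranteed to respect \code{volumeRange}. Uses the global RNG.
#'
#' @param kind "single_focal", "multi_focal" or "extended".
#' @param sourceSpace the \linkS4class{SourceSpace} to activate.
#' @param nGroups number of active groups (1 for single_focal; 2-3 typical
#'   for multi_focal; 1-2 for extended).
#' @param times trial time axis, seconds.
#' @param fs sampling frequency, Hz.
#' @param signalRanges waveform parameter ranges
#'   (\code{\link{defaultSignalRanges}}).
#' @param volumeRange extended-region volume bounds, cm^3 (default 14-44).
#' @param maxRetries bounded re-seeding attempts when growth stalls.
#' @return a \linkS4class{Scenario}
#' @export
makeScenario <- function(kind = c("single_focal", "multi_focal", "extended"),
                         sourceSpace, nGroups = NULL,
                         times = makeTimeAxis(), fs = 1000,
                         signalRanges = defaultSignalRanges(),
                         volumeRange = c(14, 44), maxRetries = 25L) {
  kind <- match.arg(kind)
  stopifnot(is(sourceSpace, "SourceSpace"))
  D <- nSources(sourceSpace)
  if (is.null(nGroups))
    nGroups <- switch(kind, single_focal = 1L, multi_focal = 2L, extended = 1L)
  if (kind == "single_focal" && nGroups != 1L)
    .stopInvalidConfig("single_focal means exactly one group")
  groups <- list()
  if (kind %in% c("single_focal", "multi_focal")) {
    # the origin dipole is magnetically silent in the spherical model and
    # cannot carry a focal activation
    candidates <- setdiff(seq_len(D), sourceSpace@originIndex)
    idx <- candidates[sample.int(length(candidates), nGroups)]
    groups <- lapply(idx, function(i)
      list(indices = as.integer(i), params = sampleSignalParams(signalRanges)))
  } else {
    vv <- voxelVolume(sourceSpace)
    lo <- ceiling(volumeRange[1] / vv); hi <- floor(volumeRange[2] / vv)
    if (lo > hi)
      stop("scenario-generation: no integer voxel count realizes a volume in [",
           volumeRange[1], ", ", volumeRange[2], "] cm^3 at voxel volume ",
           vv, " cm^3", call. = FALSE)
    lat <- .latticeIndex(sourceSpace)
    taken <- integer(0)
    for (g in seq_len(nGroups)) {
      nVox <- if (lo == hi) lo else sample(lo:hi, 1L)
      region <- NULL
      for (try in seq_len(maxRetries)) {
        # never seed on the silent origin dipole (growth may still absorb it)
        seedVoxel <- sample.int(D, 1L)
        if (seedVoxel %in% taken || seedVoxel == sourceSpace@originIndex) next
        region <- .growRegion(seedVoxel, nVox, lat, exclude = taken)
        if (!is.null(region)) break
      }
      if (is.null(region))
        stop("scenario-generation: could not grow a ", nVox,
             "-voxel region after ", maxRetries, " retries", call. = FALSE)
      taken <- c(taken, region)
      groups[[g]] <- list(indices = as.integer(sort(region)),
                          params = sampleSignalParams(signalRanges))
    }
  }
  new("Scenario", kind = kind, groups = groups, nSources = D,
      times = times, fs = fs)
}

#' Render ground-truth source activity from a scenario
#'
#' Every dipole of an active group carries its group's Gaussian-damped sine
#' evaluated on the scenario time axis; all other rows are zero.
#'
#' @param scenario a \linkS4class{Scenario}.
#' @return a \linkS4class{SourceActivity} (D x T, all columns valid)
#' @export
renderSourceActivity <- function(scenario) {
  stopifnot(is(scenario, "Scenario"))
  T <- length(scenario@times)
  A <- matrix(0, scenario@nSources, T)
  for (g in scenario@groups) {
    sig <- gaussianDampedSine(g$params, scenario@times)
    A[g$indices, ] <- rep(sig, each = length(g$indices))
  }
  new("SourceActivity", amplitudes = A, validCols = rep(TRUE, T))
}

#' Export a scenario as structured text
#'
#' JSON listing the kind, time-axis metadata, and per group the active
#' dipole indices (1-based) and waveform parameters.
#'
#' @param scenario a \linkS4class{Scenario}.
#' @param path output file; if NULL the JSON string is returned.
#' @return path (invisibly) or a JSON string.
#' @export
exportScenario <- function(scenario, path = NULL) {
  obj <- list(
    kind = scenario@kind, n_sources = scenario@nSources,
    fs = scenario@fs, n_samples = length(scenario@times),
    groups = lapply(scenario@groups, function(g)
      list(indices = g$indices,
           params = list(t0 = g$params@t0, omega = g$params@omega,
                         f0 = g$params@f0, phi = g$params@phi))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
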