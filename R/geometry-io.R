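#' @include AllClasses.R forward.R
NULL

#' Write / read geometry as delimited text
#'
#' Plain TSV with one row per sensor or dipole: columns \code{x, y, z, ox,
#' oy, oz} (meters; orientations unitless). A comment line records the units;
#' rows are 0-based in the sense that row i of the file is dipole/sensor
#' i + 1 in R's 1-based indexing.
#'
#' @param x a \linkS4class{SensorArray} or \linkS4class{SourceSpace}.
#' @param path output file path.
#' @return \code{writeGeometry} returns \code{path} invisibly;
#'   \code{readSensorArray} / \code{readSourceGrid} return the reconstructed
#'   object.
#' @export
writeGeometry <- function(x, path) {
  stopifnot(is(x, "SensorArray") || is(x, "SourceSpace"))
  hdr <- if (is(x, "SensorArray")) "# sensor geometry; units: meters"
         else sprintf("# source geometry; units: meters; spacing=%.17g; radius=%.17g; origin=%d",
                      x@spacing, x@radius, x@originIndex)
  df <- cbind(x@positions, x@orientations)
  colnames(df) <- c("x", "y", "z", "ox", "oy", "oz")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(df, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readGeomTable <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  list(header = hdr, pos = as.matrix(tab[, c("x", "y", "z")]),
       ori = as.matrix(tab[, c("ox", "oy", "oz")]))
}

#' @rdname writeGeometry
#' @param path input file path.
#' @export
readSensorArray <- function(path) {
  g <- .readGeomTable(path)
  pos <- unname(g$pos); colnames(pos) <- c("x", "y", "z")
  new("SensorArray", positions = pos, orientations = unname(g$ori))
}

#' Save / load a leadfield as an array bundle
#'
#' Stores the gain matrix together with the full sensor and source
#' geometry in the self-describing array-bundle format (shapes + MD5
#' content hashes in the manifest), so a reloaded leadfield is verified
#' bit-exact against the geometry it was built from.
#'
#' @param leadfield a \linkS4class{Leadfield}.
#' @param path bundle directory.
#' @return \code{saveLeadfield} returns \code{path} invisibly;
#'   \code{loadLeadfield} the reconstructed \linkS4class{Leadfield}.
#' @export
saveLeadfield <- function(leadfield, path) {
  stopifnot(is(leadfield, "Leadfield"))
  src <- leadfield@sources
  saveBundle(path, list(
    gain = unname(leadfield@gain),
    sensorPositions = unname(leadfield@sensors@positions),
    sensorOrientations = unname(leadfield@sensors@orientations),
    sourcePositions = unname(src@positions),
    sourceOrientations = unname(src@orientations)),
    meta = list(spacing = src@spacing, radius = src@radius,
                originIndex = src@originIndex))
  invisible(path)
}

#' @rdname saveLeadfield
#' @export
loadLeadfield <- function(path) {
  b <- loadBundle(path)
  a <- b$arrays
  pos <- a$sensorPositions; colnames(pos) <- c("x", "y", "z")
  sensors <- new("SensorArray", positions = pos,
                 orientations = a$sensorOrientations)
  sources <- new("SourceSpace", positions = a$sourcePositions,
                 orientations = a$sourceOrientations,
                 spacing = b$meta$spacing, radius = b$meta$radius,
                 originIndex = as.integer(b$meta$originIndex))
  new("Leadfield", gain = a$gain, sensors = sensors, sources = sources)
}

#' @rdname writeGeometry
#' @export
readSourceGrid <- function(path) {
  g <- .readGeomTable(path)
  m <- regmatches(g$header,
                  regexec("spacing=([0-9.eE+-]+); radius=([0-9.eE+-]+); origin=([0-9]+)",
                          g$header))[[1]]
  if (length(m) != 4L) stop("corrupt geometry header: ", g$header, call. = FALSE)
  new("SourceSpace", positions = unname(g$pos), orientations = unname(g$ori),
      spacing = as.numeric(m[2]), radius = as.numeric(m[3]),
      originIndex = as.integer(m[4]))
}
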