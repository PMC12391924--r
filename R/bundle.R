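#' @include AllClasses.R
NULL

#' Save / load a named-array bundle
#'
#' A bundle is a directory holding one raw little-endian double file per
#' array plus a \code{manifest.json} recording names, dimensions, MD5
#' content hashes, and free-form metadata. Round trips are bit-exact; the
#' manifest is validated on load and any shape or content mismatch is
#' rejected as corrupt.
#'
#' @param path bundle directory (created by \code{saveBundle}).
#' @param arrays named list of numeric vectors/matrices/arrays.
#' @param meta named list of metadata (seeds, config hashes, logs).
#' @return \code{saveBundle} returns \code{path} invisibly;
#'   \code{loadBundle} returns \code{list(arrays = ..., meta = ...)}.
#' @examples
#' p <- file.path(tempdir(), "demo-bundle")
#' saveBundle(p, list(m = matrix(1:6, 2)), meta = list(seed = 1))
#' b <- loadBundle(p)
#' @export
saveBundle <- function(path, arrays, meta = list()) {
  if (!length(names(arrays)) || any(names(arrays) == ""))
    .stopInvalidConfig("all arrays must be named")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    f <- file.path(path, paste0(nm, ".bin"))
    con <- file(f, "wb")
    writeBin(as.numeric(a), con, size = 8, endian = "little")
    close(con)
    entries[[nm]] <- list(dim = if (is.null(dim(a))) length(a) else dim(a),
                          md5 = unname(tools::md5sum(f)))
  }
  manifest <- list(format = "megsi-bundle-1", created = format(Sys.time()),
                   arrays = entries, meta = meta)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(path, "manifest.json"))
  invisible(path)
}

#' @rdname saveBundle
#' @export
loadBundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("corrupt-bundle: missing manifest in ", path,
                             call. = FALSE)
  manifest <- jsonlite::fromJSON(readLines(mf), simplifyVector = TRUE)
  if (!identical(manifest$format, "megsi-bundle-1"))
    stop("corrupt-bundle: unknown format tag", call. = FALSE)
  arrays <- list()
  for (nm in names(manifest$arrays)) {
    f <- file.path(path, paste0(nm, ".bin"))
    if (!file.exists(f)) stop("corrupt-bundle: missing array file ", nm,
                              call. = FALSE)
    if (!identical(unname(tools::md5sum(f)), manifest$arrays[[nm]]$md5))
      stop("corrupt-bundle: content hash mismatch for ", nm, call. = FALSE)
    dm <- as.integer(manifest$arrays[[nm]]$dim)
    n <- prod(dm)
    con <- file(f, "rb")
    v <- readBin(con, "numeric", n = n + 1L, size = 8, endian = "little")
    close(con)
    if (length(v) != n)
      stop("corrupt-bundle: ", nm, " holds ", length(v),
           " values but the manifest declares ", n, call. = FALSE)
    if (length(dm) > 1L) dim(v) <- dm
    arrays[[nm]] <- v
  }
  list(arrays = arrays, meta = manifest$meta)
}
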