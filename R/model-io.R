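#' @include AllClasses.R network.R bundle.R
NULL

#' Save / load a trained model as a directory bundle
#'
#' The architecture and scalers are written as JSON, the training history
#' as CSV, and every parameter tensor in the bit-exact array-bundle format,
#' so \code{loadModel(saveModel(m))} reproduces predictions exactly.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param path directory to create.
#' @return \code{saveModel} returns \code{path} invisibly;
#'   \code{loadModel} the reconstructed \linkS4class{TrainedModel}.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- model@config
  arch <- list(W = cfg@W, convFeatures = cfg@convFeatures,
               convKernels = cfg@convKernels, fcLayers = cfg@fcLayers,
               fcWidth = cfg@fcWidth, nSensors = cfg@nSensors,
               nSources = cfg@nSources)
  writeLines(jsonlite::toJSON(arch, auto_unbox = TRUE, digits = NA),
             file.path(path, "architecture.json"))
  arrays <- list(inputMean = model@inputMean, inputSd = model@inputSd,
                 targetScale = model@targetScale)
  p <- model@params
  for (l in seq_along(p$conv)) {
    arrays[[sprintf("conv%d_W", l)]] <- p$conv[[l]]$W
    arrays[[sprintf("conv%d_b", l)]] <- p$conv[[l]]$b
  }
  for (l in seq_along(p$bn)) {
    arrays[[sprintf("bn%d_gamma", l)]] <- p$bn[[l]]$gamma
    arrays[[sprintf("bn%d_beta", l)]] <- p$bn[[l]]$beta
    arrays[[sprintf("bn%d_runMean", l)]] <- p$bn[[l]]$runMean
    arrays[[sprintf("bn%d_runVar", l)]] <- p$bn[[l]]$runVar
  }
  for (l in seq_along(p$fc)) {
    arrays[[sprintf("fc%d_W", l)]] <- p$fc[[l]]$W
    arrays[[sprintf("fc%d_b", l)]] <- p$fc[[l]]$b
  }
  saveBundle(file.path(path, "weights"), arrays,
             meta = list(nConv = length(p$conv), nBn = length(p$bn),
                         nFc = length(p$fc)))
  utils::write.csv(model@history, file.path(path, "history.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  arch <- jsonlite::fromJSON(readLines(file.path(path, "architecture.json")))
  cfg <- networkConfig(nSensors = arch$nSensors, nSources = arch$nSources,
                       W = arch$W, convFeatures = arch$convFeatures,
                       convKernels = arch$convKernels,
                       fcLayers = arch$fcLayers, fcWidth = arch$fcWidth)
  b <- loadBundle(file.path(path, "weights"))
  a <- b$arrays
  conv <- lapply(seq_len(b$meta$nConv), function(l)
    list(W = a[[sprintf("conv%d_W", l)]], b = as.numeric(a[[sprintf("conv%d_b", l)]]),
         k = cfg@convKernels[l]))
  bn <- lapply(seq_len(b$meta$nBn), function(l)
    list(gamma = as.numeric(a[[sprintf("bn%d_gamma", l)]]),
         beta = as.numeric(a[[sprintf("bn%d_beta", l)]]),
         runMean = as.numeric(a[[sprintf("bn%d_runMean", l)]]),
         runVar = as.numeric(a[[sprintf("bn%d_runVar", l)]])))
  fc <- lapply(seq_len(b$meta$nFc), function(l)
    list(W = a[[sprintf("fc%d_W", l)]], b = as.numeric(a[[sprintf("fc%d_b", l)]])))
  hist <- utils::read.csv(file.path(path, "history.csv"))
  new("TrainedModel", params = list(conv = conv, bn = bn, fc = fc),
      config = cfg, inputMean = as.numeric(a$inputMean),
      inputSd = as.numeric(a$inputSd),
      targetScale = as.numeric(a$targetScale), history = hist)
}
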