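#' @include AllClasses.R config.R training-set.R network.R inverse.R metrics.R
NULL

#' Build the geometries and leadfields of a run configuration
#'
#' Constructs the sensor helmet, the (fine) forward source grid used to
#' simulate data and drive the classical solvers, and the (coarse) inverse
#' grid the network reconstructs on, with their leadfields. When the two
#' spacings are equal a single grid is shared.
#'
#' @param config a \linkS4class{RunConfig}.
#' @return list with \code{sensors}, \code{forwardSpace},
#'   \code{forwardLeadfield}, \code{inverseSpace}, \code{inverseLeadfield}.
#' @export
setupGeometry <- function(config) {
  stopifnot(is(config, "RunConfig"))
  g <- config@geometry
  sensors <- buildSensorHelmet(g$nSensors, g$sensorRadius, g$capFraction)
  fwd <- buildSourceGrid(g$sourceRadius, g$forwardSpacing, g$orientationSeed)
  fwdLf <- assembleLeadfield(sensors, fwd)
  if (isTRUE(all.equal(g$forwardSpacing, g$inverseSpacing))) {
    inv <- fwd; invLf <- fwdLf
  } else {
    inv <- buildSourceGrid(g$sourceRadius, g$inverseSpacing, g$orientationSeed)
    invLf <- assembleLeadfield(sensors, inv)
  }
  list(sensors = sensors, forwardSpace = fwd, forwardLeadfield = fwdLf,
       inverseSpace = inv, inverseLeadfield = invLf)
}

#' Generate a training set and fit the network per a run configuration
#'
#' Windows are simulated on the inverse grid (the grid the network
#' reconstructs), with the configured signal model, SNR range and
#' focal/extended mix, then the network is trained with the configured
#' optimizer settings.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param geometry output of \code{\link{setupGeometry}} (rebuilt if NULL).
#' @return a fitted \linkS4class{TrainedModel}
#' @export
trainFromConfig <- function(config, geometry = NULL) {
  stopifnot(is(config, "RunConfig"))
  if (is.null(geometry)) geometry <- setupGeometry(config)
  d <- config@dataset; s <- config@signal; tr <- config@training
  ranges <- s[c("t0", "omega", "f0", "phi")]
  times <- makeTimeAxis(s$duration, s$fs)
  ts <- buildTrainingSet(d$nExamples, geometry$inverseSpace,
                         geometry$inverseLeadfield,
                         focalFraction = d$focalFraction, W = d$W,
                         snrRange = d$snrRange, times = times,
                         volumeRange = d$volumeRange, signalRanges = ranges,
                         seed = tr$seed)
  n <- config@network
  cfg <- networkConfig(nSensors = nSensors(geometry$inverseLeadfield),
                       nSources = nSources(geometry$inverseSpace),
                       W = d$W, convFeatures = n$convFeatures,
                       convKernels = n$convKernels,
                       fcLayers = n$fcLayers, fcWidth = n$fcWidth)
  tc <- trainConfig(epochs = tr$epochs, learningRate = tr$learningRate,
                    batchSize = tr$batchSize, seed = tr$seed,
                    valFraction = tr$valFraction)
  trainModel(buildNetwork(cfg, initSeed = tr$seed), ts, config = tc)
}

# nearest-voxel mapping of positions into a target source space
.mapToSpace <- function(positions, space) {
  vapply(seq_len(nrow(positions)), function(i) {
    d2 <- rowSums(sweep(space@positions, 2, positions[i, ], "-")^2)
    which.min(d2)
  }, integer(1))
}

.runSolver <- function(method, recording, geom, model, bench) {
  if (method == "network") {
    est <- reconstructTimeseries(model, recording)
    list(amplitudes = est@amplitudes, valid = est@validCols,
         space = geom$inverseSpace)
  } else {
    lf <- geom$forwardLeadfield
    sol <- switch(method,
      lcmv = solveLCMV(lf, estimateCovariance(recording, bench$lcmvLoading),
                       recording),
      mne = solveMNE(lf, recording),
      eloreta = solveELORETA(lf, recording),
      rv = solveRVScan(lf, recording))
    list(amplitudes = sol@amplitudes,
         valid = rep(TRUE, ncol(sol@amplitudes)),
         space = geom$forwardSpace)
  }
}

.caseMetrics <- function(res, activity, scenario, geom, bench) {
  thr <- bench$thresholdFraction
  trueIdx <- sort(unlist(lapply(scenario@groups, `[[`, "indices")))
  truePos <- geom$forwardSpace@positions[trueIdx, , drop = FALSE]
  estA <- suppressWarnings(
    activeSet(res$amplitudes[, res$valid, drop = FALSE], thr))
  estPos <- res$space@positions[estA@indices, , drop = FALSE]
  out <- list(dle = as.numeric(dle(truePos, estPos)),
              av = activeVolume(estA, res$space))
  # IoU over the estimate's grid; truth mapped by nearest voxel if needed
  trueOnSpace <- if (identical(dim(res$space@positions),
                               dim(geom$forwardSpace@positions)) &&
                     isTRUE(all.equal(res$space@positions,
                                      geom$forwardSpace@positions)))
    trueIdx else unique(.mapToSpace(truePos, res$space))
  u <- union(trueOnSpace, estA@indices)
  out$iou <- if (length(u)) 100 * length(intersect(trueOnSpace, estA@indices)) /
    length(u) else 0
  # envelope NRMSE: best-matching active estimated trace per true source
  if (length(estA@indices)) {
    vals <- vapply(seq_along(trueIdx), function(k) {
      d2 <- rowSums(sweep(estPos, 2, truePos[k, ], "-")^2)
      h <- estA@indices[which.min(d2)]
      tt <- activity@amplitudes[trueIdx[k], res$valid]
      et <- res$amplitudes[h, res$valid]
      if (sum(tt^2) == 0 || sum(et^2) == 0) return(NA_real_)
      nrmse(tt, et)
    }, numeric(1))
    out$nrmse <- mean(vals, na.rm = TRUE)
  } else out$nrmse <- NA_real_
  out
}

#' Run the simulated benchmark
#'
#' For every scenario kind in the configuration, generates
#' \code{nTestCases} seeded ground-truth trials on the forward grid; the
#' same clean trials are re-noised at every test SNR (paired comparisons).
#' Every requested method then reconstructs each noisy recording — the
#' network on the inverse grid, the classical solvers on the forward grid —
#' and the localization/reconstruction metrics are computed against the
#' ground truth in physical space. Solvers never see the true activity;
#' only the forward operator is shared.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param model a fitted \linkS4class{TrainedModel}; trained from the
#'   configuration when NULL and "network" is among the methods.
#' @param geometry optional precomputed \code{\link{setupGeometry}} output.
#' @param outDir when non-NULL, per-case and summary CSV tables plus a run
#'   manifest are written there.
#' @return list with \code{perCase} (one row per case x SNR x method) and
#'   \code{summary} (mean and sd per method x kind x SNR x metric),
#'   invisibly also written as CSV when \code{outDir} is given.
#' @export
runBenchmark <- function(config, model = NULL, geometry = NULL, outDir = NULL) {
  stopifnot(is(config, "RunConfig"))
  if (is.null(geometry)) geometry <- setupGeometry(config)
  bench <- config@benchmark
  s <- config@signal
  times <- makeTimeAxis(s$duration, s$fs)
  ranges <- s[c("t0", "omega", "f0", "phi")]
  if ("network" %in% bench$methods && is.null(model))
    model <- trainFromConfig(config, geometry)
  rows <- list()
  .withSeed(bench$seed, {
    for (kind in bench$kinds) {
      nGroups <- switch(kind, single_focal = 1L, multi_focal = 3L, extended = 1L)
      cases <- lapply(seq_len(bench$nTestCases), function(i) {
        sc <- makeScenario(kind, geometry$forwardSpace, nGroups = nGroups,
                           times = times, signalRanges = ranges,
                           volumeRange = config@dataset$volumeRange)
        list(scenario = sc, activity = renderSourceActivity(sc),
             noiseSeeds = sample.int(.Machine$integer.max,
                                     length(bench$testSnrDb)))
      })
      for (ci in seq_along(cases)) {
        cs <- cases[[ci]]
        for (si in seq_along(bench$testSnrDb)) {
          snr <- bench$testSnrDb[si]
          rec <- simulateRecording(cs$activity, geometry$forwardLeadfield,
                                   snrDb = snr, noiseSeed = cs$noiseSeeds[si])
          for (method in bench$methods) {
            res <- tryCatch(
              .runSolver(method, rec, geometry, model, bench),
              error = function(e) e)
            if (inherits(res, "error")) {
              rows[[length(rows) + 1L]] <- data.frame(
                kind = kind, case = ci, snrDb = snr, method = method,
                dle = NA_real_, av = NA_real_, iou = NA_real_,
                nrmse = NA_real_, failed = TRUE,
                error = conditionMessage(res))
              next
            }
            m <- .caseMetrics(res, cs$activity, cs$scenario, geometry, bench)
            rows[[length(rows) + 1L]] <- data.frame(
              kind = kind, case = ci, snrDb = snr, method = method,
              dle = m$dle, av = m$av, iou = m$iou, nrmse = m$nrmse,
              failed = FALSE, error = "")
          }
        }
      }
    }
  })
  perCase <- do.call(rbind, rows)
  ok <- perCase[!perCase$failed, ]
  ok$dleFinite <- ifelse(is.finite(ok$dle), ok$dle, NA_real_)
  summ <- NULL
  for (metric in c("dleFinite", "av", "iou", "nrmse")) {
    sub <- ok[, c("method", "kind", "snrDb", metric)]
    names(sub)[4] <- "value"
    if (all(is.na(sub$value))) next
    mean_ <- stats::aggregate(value ~ method + kind + snrDb, sub, mean,
                              na.action = stats::na.omit)
    sd_ <- stats::aggregate(value ~ method + kind + snrDb, sub, stats::sd,
                            na.action = stats::na.omit)
    mean_$sd <- sd_$value
    mean_$metric <- ifelse(metric == "dleFinite", "dle", metric)
    names(mean_)[names(mean_) == "value"] <- "mean"
    summ <- rbind(summ, mean_[, c("method", "kind", "snrDb", "metric",
                                  "mean", "sd")])
  }
  nExcluded <- sum(perCase$failed) + sum(!is.finite(perCase$dle), na.rm = TRUE)
  attr(summ, "excluded") <- nExcluded
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(perCase, file.path(outDir, "per_case.csv"),
                     row.names = FALSE)
    utils::write.csv(summ, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
    saveRunConfig(config, file.path(outDir, "run_config.yaml"))
  }
  list(perCase = perCase, summary = summ)
}
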