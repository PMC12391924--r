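test_that("covariance estimation matches the sample estimator", {
  geo <- tinyGeometry(nSensors = 6)
  flat <- new("SensorRecording", samples = matrix(1, 6, 50),
              clean = matrix(1, 6, 50), snrDb = Inf, noiseSeed = NA_integer_)
  cv <- estimateCovariance(flat, 0.05)
  expect_equal(cv@matrix, matrix(0, 6, 6))

  set.seed(13)
  M <- matrix(stats::rnorm(6 * 200), 6, 200)
  rec <- new("SensorRecording", samples = M, clean = M * 0, snrDb = 0,
             noiseSeed = 1L)
  cv0 <- estimateCovariance(rec, 0)
  expect_equal(cv0@matrix, unname(stats::cov(t(M))), tolerance = 1e-12)

  # white noise of known sigma: diagonal within 5% at T = 10000
  sigma <- 2.5
  N <- matrix(stats::rnorm(4 * 10000, sd = sigma), 4, 10000)
  recN <- new("SensorRecording", samples = N, clean = N * 0, snrDb = 0,
              noiseSeed = 1L)
  d <- diag(estimateCovariance(recN, 0)@matrix)
  expect_true(all(abs(d - sigma^2) / sigma^2 < 0.05))

  one <- new("SensorRecording", samples = matrix(1, 3, 1),
             clean = matrix(1, 3, 1), snrDb = Inf, noiseSeed = NA_integer_)
  expect_error(estimateCovariance(one), "insufficient-data")
})

test_that("LCMV satisfies unit gain and matches a KKT oracle", {
  geo <- tinyGeometry(nSensors = 6, sourceRadius = 0.05, spacing = 0.035)
  set.seed(17)
  sc <- makeScenario("single_focal", geo$grid)
  act <- renderSourceActivity(sc)
  rec <- simulateRecording(act, geo$lf, snrDb = 20, noiseSeed = 3L)
  cv <- estimateCovariance(rec, 0.05)
  sol <- solveLCMV(geo$lf, cv, rec)

  L <- gain(geo$lf); C <- cv@matrix; Cinv <- solve(C)
  for (i in seq_len(ncol(L))) {
    l <- L[, i]
    if (sum(l^2) == 0) next
    w <- Cinv %*% l / as.numeric(t(l) %*% Cinv %*% l)
    expect_lt(abs(sum(w * l) - 1), 1e-8)   # unit gain
    # independent oracle: KKT system of min w'Cw s.t. w'l = 1
    kkt <- solve(rbind(cbind(2 * C, l), c(l, 0)),
                 c(numeric(length(l)), 1))
    wOracle <- unname(kkt[seq_along(l)])
    expect_equal(as.numeric(w), wOracle, tolerance = 1e-6)
    expect_equal(sol@amplitudes[i, ], as.numeric(t(w) %*% samples(rec)),
                 tolerance = 1e-8)
  }

  # noiseless single source: output power peaks at the true dipole
  clean <- simulateRecording(act, geo$lf, snrDb = Inf)
  cvc <- estimateCovariance(clean, 0.05)
  solc <- solveLCMV(geo$lf, cvc, clean)
  pw <- rowSums(solc@amplitudes^2)
  expect_equal(which.max(pw), sc@groups[[1]]$indices)
})

test_that("MNE obeys its shrinkage and interpolation limits", {
  geo <- tinyGeometry(nSensors = 6, sourceRadius = 0.05, spacing = 0.035)
  set.seed(19)
  sc <- makeScenario("single_focal", geo$grid)
  rec <- simulateRecording(renderSourceActivity(sc), geo$lf, snrDb = 20,
                           noiseSeed = 5L)
  big <- solveMNE(geo$lf, rec, lambda = 1e15 * sum(gain(geo$lf)^2))
  expect_lt(max(abs(big@amplitudes)), 1e-6 * max(abs(samples(rec))))

  mkRec <- function(M) new("SensorRecording", samples = M, clean = M,
                           snrDb = Inf, noiseSeed = NA_integer_)

  # square invertible toy (S = D = 4): lambda = 0 interpolates exactly
  grid4 <- customSourceSpace(rbind(c(1, 0, 0), c(0, 1, 0),
                                   c(0, 0, 1), c(1, 1, 0)))
  lf4 <- assembleLeadfield(buildSensorHelmet(4, 0.12), grid4)
  L4 <- gain(lf4)
  expect_equal(nrow(L4), 4L); expect_equal(ncol(L4), 4L)
  set.seed(20)
  M4 <- matrix(stats::rnorm(4 * 9), 4, 9) * 1e-7
  solInt <- solveMNE(lf4, mkRec(M4), lambda = 0)
  expect_equal(L4 %*% solInt@amplitudes, M4, tolerance = 1e-8)

  # underdetermined toy (S = 3, D = 6): tiny lambda matches the
  # pseudoinverse and has minimal norm among exact-fit solutions
  grid6 <- customSourceSpace(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                   c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)))
  lf36 <- assembleLeadfield(buildSensorHelmet(3, 0.12), grid6)
  L36 <- gain(lf36)
  set.seed(21)
  M3 <- matrix(stats::rnorm(3 * 5), 3, 5) * 1e-7
  tiny <- 1e-10 * sum(diag(tcrossprod(L36))) / 3
  sol36 <- solveMNE(lf36, mkRec(M3), lambda = tiny)
  pinvSol <- MASS::ginv(L36) %*% M3
  expect_equal(sol36@amplitudes, pinvSol, tolerance = 1e-4)
  # any exact-fit perturbation in the null space only increases the norm
  ns <- svd(L36, nv = 6)$v[, 4:6]
  for (k in 1:5) {
    alt <- pinvSol + ns %*% matrix(stats::rnorm(3 * 5), 3, 5) *
      sqrt(mean(pinvSol^2))
    expect_gt(sum(alt^2), sum(sol36@amplitudes^2))
  }
})

test_that("eLORETA localizes noiseless grid dipoles exactly at any depth", {
  geo <- tinyGeometry(nSensors = 24, sourceRadius = 0.06, spacing = 0.02)
  rad <- sqrt(rowSums(geo$grid@positions^2))
  deep <- which(rad == min(rad[rad > 0]))[1]
  shallow <- which.max(rad)
  set.seed(23)
  for (d in c(deep, shallow)) {
    sc <- focalScenario(d, geo$grid)
    rec <- simulateRecording(renderSourceActivity(sc), geo$lf, snrDb = Inf)
    sol <- solveELORETA(geo$lf, rec)
    expect_true(sol@info$converged)
    expect_true(all(sol@info$weights > 0))
    expect_equal(which.max(rowSums(sol@amplitudes^2)), d)
  }

  # fixed point: one extra iteration moves the weights by < tol
  sc <- focalScenario(shallow, geo$grid)
  rec <- simulateRecording(renderSourceActivity(sc), geo$lf, snrDb = Inf)
  sol <- solveELORETA(geo$lf, rec, tol = 1e-8)
  w <- sol@info$weights
  L <- gain(geo$lf); S <- nrow(L)
  alpha <- sol@hyperparameters$alpha
  Minner <- megsi:::.pinvSym(tcrossprod(sweep(L, 2, w, "/"), L) +
                               diag(alpha, S))
  wNext <- sqrt(pmax(colSums(L * (Minner %*% L)), 0))
  wNext[wNext == 0] <- min(wNext[wNext > 0])
  expect_lt(max(abs(wNext - w) / w), 1e-6)
})

test_that("RV scan reproduces per-dipole least-squares residuals", {
  geo <- tinyGeometry(nSensors = 8, sourceRadius = 0.05, spacing = 0.035)
  set.seed(29)
  sc <- makeScenario("single_focal", geo$grid)
  rec <- simulateRecording(renderSourceActivity(sc), geo$lf, snrDb = Inf)
  sol <- solveRVScan(geo$lf, rec)
  expect_true(all(sol@scores >= 0 & sol@scores <= 1))
  expect_lt(sol@scores[sc@groups[[1]]$indices], 1e-10)
  expect_equal(sol@info$best, sc@groups[[1]]$indices)

  # oracle: generic least-squares residual per dipole
  M <- samples(rec); L <- gain(geo$lf)
  for (i in seq_len(ncol(L))) {
    l <- L[, i]
    if (sum(l^2) == 0) { expect_equal(sol@scores[i], 1); next }
    fit <- stats::lsfit(l, M, intercept = FALSE)
    rv <- sum(fit$residuals^2) / sum(M^2)
    expect_lt(abs(sol@scores[i] - rv), 1e-10)
  }

  zeroRec <- new("SensorRecording", samples = matrix(0, 8, 5),
                 clean = matrix(0, 8, 5), snrDb = Inf, noiseSeed = NA_integer_)
  expect_error(solveRVScan(geo$lf, zeroRec), "zero")
})

test_that("eLORETA localization degrades under strong sensor noise", {
  # under heavy noise (0 dB) the 50%-energy active set starts missing the
  # true dipole; at moderate noise (10 dB in this spherical geometry) it
  # does not — the thresholded DLE is a step function of noise level
  sensors <- buildSensorHelmet(32, 0.12, 0.6)
  grid <- buildSourceGrid(0.07, 0.015)
  lf <- assembleLeadfield(sensors, grid)
  set.seed(99)
  d0 <- vapply(seq_len(15), function(i) {
    sc <- makeScenario("single_focal", grid)
    rec <- simulateRecording(renderSourceActivity(sc), lf, snrDb = 0)
    a <- suppressWarnings(activeSet(solveELORETA(lf, rec)@amplitudes))
    as.numeric(dle(grid@positions[sc@groups[[1]]$indices, , drop = FALSE],
                   grid@positions[a@indices, , drop = FALSE]))
  }, numeric(1))
  expect_gt(mean(d0), 15)   # localization visibly broken at 0 dB
})

test_that("solvers are deterministic", {
  geo <- tinyGeometry(nSensors = 10, sourceRadius = 0.05, spacing = 0.035)
  set.seed(31)
  sc <- makeScenario("single_focal", geo$grid)
  rec <- simulateRecording(renderSourceActivity(sc), geo$lf, snrDb = 15,
                           noiseSeed = 9L)
  cv <- estimateCovariance(rec)
  expect_identical(solveLCMV(geo$lf, cv, rec)@amplitudes,
                   solveLCMV(geo$lf, cv, rec)@amplitudes)
  expect_identical(solveMNE(geo$lf, rec)@amplitudes,
                   solveMNE(geo$lf, rec)@amplitudes)
  expect_identical(solveELORETA(geo$lf, rec)@amplitudes,
                   solveELORETA(geo$lf, rec)@amplitudes)
  expect_identical(solveRVScan(geo$lf, rec)@scores,
                   solveRVScan(geo$lf, rec)@scores)
})
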