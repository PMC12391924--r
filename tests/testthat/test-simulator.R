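test_that("signal parameters are uniform within their ranges", {
  deg <- lapply(c(t0 = 0.1, omega = 0.05, f0 = 10, phi = 1), function(v) c(v, v))
  p <- sampleSignalParams(deg)
  expect_equal(c(p@t0, p@omega, p@f0, p@phi), c(0.1, 0.05, 10, 1))

  expect_error(sampleSignalParams(list(t0 = c(1, 0), omega = c(0, 1),
                                       f0 = c(1, 2), phi = c(0, 1))),
               "invalid-config")

  set.seed(1)
  draws <- replicate(10000, {
    p <- sampleSignalParams()
    c(p@t0, p@omega, p@f0, p@phi)
  })
  rng <- defaultSignalRanges()
  expect_true(all(draws[1, ] >= 0.05 & draws[1, ] <= 0.3))
  expect_true(all(draws[2, ] >= 0.04 & draws[2, ] <= 0.12))
  expect_true(all(draws[3, ] >= 8))
  expect_lte(max(draws[3, ]), 14)
  expect_true(all(draws[4, ] >= 0 & draws[4, ] < 2 * pi))
  # KS statistic against uniform, below the 1% critical value 1.63/sqrt(n)
  for (i in 1:4) {
    r <- rng[[i]]
    stat <- suppressWarnings(
      stats::ks.test(draws[i, ], "punif", r[1], r[2])$statistic)
    expect_lt(unname(stat), 1.63 / sqrt(10000))
  }
})

test_that("the damped sinusoid follows its closed form", {
  t <- makeTimeAxis()
  expect_length(t, 400L)

  f0 <- 11; t0 <- 0.21
  p <- new("SignalParams", t0 = t0, omega = 0.07, f0 = f0,
           phi = pi / 2 - 2 * pi * f0 * t0)
  expect_equal(gaussianDampedSine(p, t0), 1)

  p2 <- new("SignalParams", t0 = 0.2, omega = 0.08, f0 = 10, phi = 0)
  g <- gaussianDampedSine(p2, t)
  expect_true(all(abs(g) <= exp(-(t - 0.2)^2 / 0.08^2) + 1e-15))
  # term-by-term reference evaluation at one point
  expect_equal(gaussianDampedSine(p2, 0.25),
               sin(2 * pi * 10 * 0.25) * exp(-(0.25 - 0.2)^2 / 0.08^2))

  expect_error(gaussianDampedSine(new("SignalParams", t0 = 0.1, omega = 1,
                                      f0 = 10, phi = 0), c(0.2, 0.1)),
               "increasing")
  expect_error(new("SignalParams", t0 = 0.1, omega = 0, f0 = 10, phi = 0))
})

test_that("focal scenarios activate distinct singleton dipoles", {
  grid <- buildSourceGrid(0.06, 0.02)
  set.seed(3)
  sc <- makeScenario("single_focal", grid)
  expect_length(sc@groups, 1L)
  expect_length(sc@groups[[1]]$indices, 1L)

  sc3 <- makeScenario("multi_focal", grid, nGroups = 3L)
  idx <- unlist(lapply(sc3@groups, `[[`, "indices"))
  expect_length(unique(idx), 3L)
  # the silent origin dipole is never an active focal source
  expect_false(grid@originIndex %in% idx)
})

test_that("extended regions are connected with volumes in range", {
  grid <- buildSourceGrid(0.06, 0.02)  # voxel = 8 cm^3
  vv <- voxelVolume(grid)
  set.seed(11)
  for (i in 1:200) {
    sc <- makeScenario("extended", grid)
    idx <- sc@groups[[1]]$indices
    vol <- length(idx) * vv
    expect_gte(vol, 14)
    expect_lte(vol, 44)
    expect_true(bfsConnected(idx, grid))
  }
  set.seed(12)
  sc2 <- makeScenario("extended", grid, nGroups = 2L)
  expect_length(sc2@groups, 2L)
  expect_length(intersect(sc2@groups[[1]]$indices, sc2@groups[[2]]$indices), 0L)
})

test_that("rendered activity has group-shared rows and zeros elsewhere", {
  grid <- buildSourceGrid(0.06, 0.02)
  set.seed(5)
  empty <- new("Scenario", kind = "single_focal", groups = list(),
               nSources = nSources(grid), times = makeTimeAxis(), fs = 1000)
  expect_equal(renderSourceActivity(empty)@amplitudes,
               matrix(0, nSources(grid), 400))

  sc <- makeScenario("extended", grid)
  act <- renderSourceActivity(sc)
  expect_equal(ncol(act@amplitudes), 400L)
  idx <- sc@groups[[1]]$indices
  for (i in idx[-1])
    expect_identical(act@amplitudes[i, ], act@amplitudes[idx[1], ])
  expect_equal(sum(rowSums(abs(act@amplitudes)) > 0), length(idx))
})

test_that("sensor noise hits the requested SNR and is white", {
  geo <- tinyGeometry(nSensors = 32)
  set.seed(8)
  sc <- makeScenario("single_focal", geo$grid)
  act <- renderSourceActivity(sc)

  clean <- simulateRecording(act, geo$lf, snrDb = Inf)
  expect_equal(samples(clean), gain(geo$lf) %*% act@amplitudes)

  rec <- simulateRecording(act, geo$lf, snrDb = 10, noiseSeed = 4L)
  expect_lt(abs(realizedSnr(rec) - 10), 0.5)

  # whiteness: mean lag-1 autocorrelation of the noise across sensors
  noise <- samples(rec) - rec@clean
  rho <- apply(noise, 1, function(x)
    stats::cor(x[-length(x)], x[-1]))
  expect_lt(abs(mean(rho)), 3 / sqrt(ncol(noise)))

  # superposition of noiseless recordings
  sc2 <- makeScenario("single_focal", geo$grid)
  act2 <- renderSourceActivity(sc2)
  both <- act@amplitudes + act2@amplitudes
  sumRec <- simulateRecording(new("SourceActivity", amplitudes = both,
                                  validCols = act@validCols),
                              geo$lf, snrDb = Inf)
  expect_equal(samples(sumRec), samples(clean) +
                 samples(simulateRecording(act2, geo$lf, snrDb = Inf)))

  zero <- new("SourceActivity",
              amplitudes = matrix(0, nSources(geo$grid), 400),
              validCols = rep(TRUE, 400))
  expect_error(simulateRecording(zero, geo$lf, snrDb = 10), "undefined-SNR")
})

test_that("training sets are split, windowed, and reproducible", {
  geo <- tinyGeometry(nSensors = 16, sourceRadius = 0.06, spacing = 0.02)
  ts <- buildTrainingSet(100, geo$grid, geo$lf, seed = 21L)
  expect_equal(sum(ts@kinds == "focal"), 50L)
  expect_equal(sum(ts@kinds == "extended"), 50L)
  expect_equal(dim(ts@windows), c(100L, 16L, 21L))
  expect_true(all(ts@snrDb >= 0 & ts@snrDb <= 30))
  half <- 10L
  expect_true(all(ts@centers >= half + 1L & ts@centers <= 400L - half))
  # focal targets activate at most one dipole
  nAct <- rowSums(ts@targets[ts@kinds == "focal", ] != 0)
  expect_true(all(nAct <= 1))

  ts2 <- buildTrainingSet(100, geo$grid, geo$lf, seed = 21L)
  expect_identical(ts@windows, ts2@windows)
  expect_identical(ts@targets, ts2@targets)

  expect_error(buildTrainingSet(10, geo$grid, geo$lf, W = 20L), "invalid-config")
  expect_error(buildTrainingSet(10, geo$grid, geo$lf, W = 401L), "invalid-config")
})
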