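# small architecture used throughout: keeps optimization tests fast while
# exercising every layer type
smallConfig <- function(S = 8L, D = 12L)
  networkConfig(S, D, W = 21L, fcLayers = 2L, fcWidth = 64L)

test_that("architecture validates its kernel schedule and shapes", {
  cfg <- networkConfig(32, 60)
  expect_equal(cfg@convKernels, c(5L, 5L, 3L, 11L))
  expect_equal(cfg@convFeatures[length(cfg@convFeatures)], 128L)

  err <- tryCatch(networkConfig(8, 10, W = 21, convKernels = c(3L, 3L, 3L, 3L)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "invalid-architecture")
  expect_match(err, "19 -> 17 -> 15 -> 13")  # achievable extents listed

  net <- buildNetwork(smallConfig())
  w <- matrix(stats::rnorm(8 * 21), 8, 21)
  expect_length(predictWindow(net, w), 12L)
})

test_that("the conv block ends with S rows of 128 features", {
  cfg <- networkConfig(5, 7)
  net <- buildNetwork(cfg, initSeed = 3L)
  X <- array(stats::rnorm(3 * 5 * 21), c(3, 5, 21))
  fw <- megsi:::.netForward(net@params, cfg, X)
  lastConv <- fw$cache$conv[[length(fw$cache$conv)]]
  expect_equal(lastConv$Tout, 1L)          # temporal axis fully collapsed
  expect_equal(dim(fw$pred), c(3L, 7L))
  # flattened feature width = S sensors x 128 features
  expect_equal(ncol(fw$cache$fcIn[[1]]), 5L * 128L)
})

test_that("parameter count matches a layer-by-layer arithmetic tally", {
  cfg <- networkConfig(32, 60, W = 21)
  net <- buildNetwork(cfg)
  # conv: kernels 5,5,3,11; features 1->16->32->64->128
  tally <- (5 * 1 * 16 + 16) + (5 * 16 * 32 + 32) +
    (3 * 32 * 64 + 64) + (11 * 64 * 128 + 128)
  tally <- tally + 2 * (16 + 32 + 64)               # BN gamma/beta
  tally <- tally + (32 * 128) * 500 + 500           # flatten -> FC1
  tally <- tally + 5 * (500 * 500 + 500)            # FC2..FC6
  tally <- tally + 500 * 60 + 60                    # output layer
  expect_equal(nParameters(net), tally)
})

test_that("training is deterministic and overfits one batch", {
  cfg <- smallConfig()
  set.seed(33)
  X <- array(stats::rnorm(64 * 8 * 21), c(64, 8, 21))
  Y <- matrix(stats::rnorm(64 * 12), 64, 12)
  ts <- new("TrainingSet", windows = X, targets = Y,
            centers = rep(11L, 64), snrDb = rep(30, 64),
            kinds = rep("focal", 64), seed = 1L)
  tc <- trainConfig(epochs = 500, learningRate = 1e-3, batchSize = 64L,
                    valFraction = 0)
  expect_equal(tc@learningRate, 1e-3)
  expect_equal(trainConfig()@learningRate, 1e-4)  # reference defaults
  expect_equal(trainConfig()@batchSize, 64L)

  net <- trainModel(buildNetwork(cfg, initSeed = 7L), ts, config = tc)
  expect_lt(utils::tail(net@history$train, 1), 0.01 * net@history$train[1])

  net2 <- trainModel(buildNetwork(cfg, initSeed = 7L), ts, config = tc)
  expect_identical(net@params, net2@params)

  # prediction on a training window matches its target after overfitting
  p <- predictWindow(net, X[5, , ])
  expect_lt(sqrt(mean((p - Y[5, ])^2)) / stats::sd(Y), 0.15)

  # non-finite loss aborts with diagnostics (Adam step magnitude ~ lr, so
  # an absurd rate overflows the forward pass within an epoch)
  expect_error(
    trainModel(buildNetwork(cfg, initSeed = 7L), ts,
               config = trainConfig(epochs = 5, learningRate = 1e30,
                                    valFraction = 0)),
    "non-finite loss")
})

test_that("prediction respects scalers, batching, and shape contracts", {
  cfg <- smallConfig()
  net <- buildNetwork(cfg, initSeed = 9L)
  net@inputMean <- stats::rnorm(8)
  net@inputSd <- stats::runif(8, 0.5, 2)
  net@targetScale <- 3.2

  set.seed(35)
  X <- array(stats::rnorm(6 * 8 * 21), c(6, 8, 21))
  batch <- predictWindow(net, X)
  for (i in 1:6)
    expect_equal(predictWindow(net, X[i, , ]), batch[i, ], tolerance = 1e-12)

  # zero output layer -> zero de-scaled predictions
  zeroNet <- net
  zeroNet@params$fc[[3]]$W[] <- 0
  zeroNet@params$fc[[3]]$b[] <- 0
  expect_equal(predictWindow(zeroNet, X[1, , ]), numeric(12))

  expect_error(predictWindow(net, matrix(0, 7, 21)), "input-contract")
})

test_that("a model reconstructs the source time course it was trained on", {
  geo <- tinyGeometry(nSensors = 8, sourceRadius = 0.05, spacing = 0.035)
  D <- nSources(geo$grid)
  set.seed(37)
  active <- which.max(sqrt(rowSums(geo$grid@positions^2)))
  sc <- focalScenario(active, geo$grid,
                      params = new("SignalParams", t0 = 0.2, omega = 0.08,
                                   f0 = 10, phi = 0.3))
  act <- renderSourceActivity(sc)
  rec <- simulateRecording(act, geo$lf, snrDb = Inf)

  # training set = every window of this one recording
  W <- 21L; half <- 10L; T <- ncol(samples(rec))
  centers <- seq.int(half + 1L, T - half)
  wins <- array(0, c(length(centers), 8, W))
  for (i in seq_along(centers))
    wins[i, , ] <- samples(rec)[, (centers[i] - half):(centers[i] + half)]
  ts <- new("TrainingSet", windows = wins,
            targets = t(act@amplitudes[, centers]),
            centers = as.integer(centers),
            snrDb = rep(Inf, length(centers)),
            kinds = rep("focal", length(centers)), seed = 1L)
  cfg <- networkConfig(8, D, fcLayers = 2L, fcWidth = 64L)
  net <- trainModel(buildNetwork(cfg, initSeed = 11L), ts,
                    config = trainConfig(epochs = 60, learningRate = 1e-3,
                                         batchSize = 64L, valFraction = 0))

  est <- reconstructTimeseries(net, rec)
  expect_equal(sum(est@validCols), T - W + 1L)
  expect_true(all(est@amplitudes[, !est@validCols] == 0))
  r <- stats::cor(est@amplitudes[active, est@validCols],
                  act@amplitudes[active, est@validCols])
  expect_gt(r, 0.95)

  # T = W edge case: exactly one valid column
  shortRec <- new("SensorRecording", samples = samples(rec)[, 1:21],
                  clean = rec@clean[, 1:21], snrDb = Inf,
                  noiseSeed = NA_integer_)
  est1 <- reconstructTimeseries(net, shortRec)
  expect_equal(sum(est1@validCols), 1L)
  expect_error(reconstructTimeseries(
    net, new("SensorRecording", samples = samples(rec)[, 1:10],
             clean = rec@clean[, 1:10], snrDb = Inf,
             noiseSeed = NA_integer_)), "input-contract")
})

test_that("models round-trip through disk with bit-identical predictions", {
  cfg <- smallConfig()
  set.seed(39)
  X <- array(stats::rnorm(32 * 8 * 21), c(32, 8, 21))
  Y <- matrix(stats::rnorm(32 * 12), 32, 12)
  ts <- new("TrainingSet", windows = X, targets = Y, centers = rep(11L, 32),
            snrDb = rep(30, 32), kinds = rep("focal", 32), seed = 1L)
  net <- trainModel(buildNetwork(cfg, initSeed = 13L), ts,
                    config = trainConfig(epochs = 3, valFraction = 0.1))
  dir <- file.path(tempdir(), "model-roundtrip")
  saveModel(net, dir)
  net2 <- loadModel(dir)
  w <- X[3, , ]
  expect_identical(predictWindow(net, w), predictWindow(net2, w))
  expect_equal(net2@history$train, net@history$train)
})
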