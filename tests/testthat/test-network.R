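ns <- asNamespace("MetaboSR")

test_that("generator honors its shape contract and build determinism", {
  spec <- unetSpec(depth = 3, baseChannels = 4, seed = 7)
  m <- buildGenerator(spec)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  y <- ns$.unetForward(m, x)
  expect_identical(dim(y), c(64L, 64L, 1L, 1L))

  m2 <- buildGenerator(spec)
  expect_identical(m$params, m2$params)
  expect_true(all(vapply(m$params, function(p) all(is.finite(p)), TRUE)))

  expect_error(ns$.unetForward(m, array(0, c(60, 60, 1, 1))), "divisible")
  expect_error(ns$.unetForward(m, array(0, c(64, 64, 2, 1))), "channels")
})

test_that("a zero final layer makes the output the final bias map", {
  m <- buildGenerator(unetSpec(depth = 2, baseChannels = 4, seed = 3))
  m$params$final_w[] <- 0
  m$params$final_b <- 0
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_true(all(ns$.unetForward(m, x) == 0))
  m$params$final_b <- 0.25
  expect_true(all(abs(ns$.unetForward(m, x) - 0.25) < 1e-12))
})

test_that("backpropagation matches finite differences for both variants", {
  set.seed(41)
  for (variant in list(c("relu", "maxpool"), c("prelu", "strided"))) {
    # He-only init: the identity path creates exact zeros at activation
    # inputs, where two-sided finite differences straddle the ReLU kink
    spec <- unetSpec(depth = 2, baseChannels = 3, inChannels = 2,
                     activation = variant[1], downsampling = variant[2],
                     init = "he", seed = 4)
    m <- buildGenerator(spec)
    x <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))
    t <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
    f <- ns$.unetForward(m, x, keepCache = TRUE)
    g <- ns$.unetBackward(m, f$cache, 2 * (f$y - t))
    for (nm in sample(names(m$params), 6)) {
      p <- m$params[[nm]]
      i <- sample(length(p), 1)
      h <- 1e-6
      m2 <- m; m2$params[[nm]][i] <- p[i] + h
      f1 <- sum((ns$.unetForward(m2, x) - t)^2)
      m2$params[[nm]][i] <- p[i] - h
      f0 <- sum((ns$.unetForward(m2, x) - t)^2)
      num <- (f1 - f0) / (2 * h)
      expect_equal(g[[nm]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("the discriminator spec records the full-scale topology", {
  spec <- discriminatorSpec()
  expect_length(spec$channels, 8L)
  expect_true(64 %in% spec$channels && 512 %in% spec$channels)
  expect_true(all(diff(log2(spec$channels)) %in% c(0, 1)))  # doubling chain
  doubled <- c(FALSE, spec$channels[-1] > spec$channels[-8])
  expect_identical(spec$strides == 2L, doubled)  # stride 2 iff channels double
  expect_error(discriminatorSpec(inputSize = 60), "incompatible")
})

test_that("discriminator outputs are probabilities and deterministic", {
  spec <- discriminatorSpec(inputSize = 16, channels = c(4, 4, 8, 8, 16, 16,
                                                         32, 32),
                            denseWidth = 8, seed = 5)
  d <- buildDiscriminator(spec)
  x <- array(runif(16 * 16 * 1 * 3), c(16, 16, 1, 3))
  r1 <- ns$.discForward(d, x)
  expect_true(all(r1$score > 0 & r1$score < 1))
  r2 <- ns$.discForward(d, x)
  expect_identical(r1$score, r2$score)
  expect_error(ns$.discForward(d, array(0, c(8, 8, 1, 1))), "16x16")
})

test_that("at initialization the discriminator is near-uncommitted", {
  ds <- tinyDataset()
  spec <- discriminatorSpec(inputSize = 32,
                            channels = c(8, 8, 16, 16, 32, 32, 64, 64),
                            denseWidth = 32, seed = 9)
  d <- buildDiscriminator(spec)
  real <- array(unlist(lapply(ds$pairs[1:4], function(p) mapData(hrMap(p)))),
                c(32, 32, 1, 4))
  fake <- array(unlist(lapply(ds$pairs[1:4], function(p)
    bicubicUpsample(mapData(lrMap(p)), 4))), c(32, 32, 1, 4))
  sReal <- mean(ns$.discForward(d, real)$score)
  sFake <- mean(ns$.discForward(d, fake)$score)
  expect_lt(abs(sReal - sFake), 0.2)
})

test_that("the perceptual loss reduces to its closed forms", {
  x <- matrix(runif(64), 8, 8)
  expect_equal(perceptualLoss(x, x, lambda = 0), 0)
  expect_equal(perceptualLoss(x, x + 0.1, lambda = 0), 0.01 * 64,
               tolerance = 1e-12)
  expect_equal(perceptualLoss(x, x, discScore = exp(-1), lambda = 1), 1,
               tolerance = 1e-12)
  expect_error(perceptualLoss(x, x, discScore = 1.2, lambda = 1), "\\(0, 1\\)")
  expect_error(perceptualLoss(x, x, lambda = -1), ">= 0")
})

test_that("checkpoints restore predictions bit-exactly", {
  m <- buildGenerator(unetSpec(depth = 2, baseChannels = 4, seed = 11))
  path <- withr::local_tempfile(fileext = ".rds")
  saveNetworkParams(m, path)
  m2 <- loadNetworkParams(path)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(ns$.unetForward(m2, x), ns$.unetForward(m, x))
  expect_error(loadNetworkParams(withr::local_tempfile(fileext = ".rds",
                                                       lines = "x")),
               "checkpoint|read")
})

test_that("full-scale training defaults record the full-scale schedule", {
  cfg <- trainConfig()
  expect_equal(cfg$batchSize, 16L)
  expect_equal(cfg$learningRate, 1e-4)
  expect_equal(cfg$iterations, 20000L)
  g <- ganConfig()
  expect_equal(g$beta1, 0.9)
  expect_equal(g$beta2, 0.999)
  expect_equal(.lr <- g$learningRate(10000), 1e-5)
  expect_equal(g$learningRate(10001), 1e-6)
})
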