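# Desk-scale learning behavior on tiny phantoms (32x32 HR, 8x8 LR).
# The full-scale relative-improvement benchmark lives in test-acceptance.R.

tinyTrainCfg <- function(iterations = 60L, seed = 21L, lr = 1e-3, ...)
  trainConfig(lambda = 0, batchSize = 4L, iterations = iterations,
              learningRate = lr, cropSize = NULL,
              generator = unetSpec(depth = 2, baseChannels = 4, seed = seed),
              logEvery = 20L, seed = seed, ...)

test_that("a zero learning rate leaves the parameters unchanged", {
  ds <- tinyDataset()
  cfg <- tinyTrainCfg(iterations = 5L, lr = 0)
  tr <- trainUnet(ds$pairs, cfg)
  expect_identical(tr$model$params,
                   buildGenerator(cfg$generator)$params)
})

test_that("short MSE training decreases the loss on a small pair set", {
  ds <- tinyDataset()
  tr <- trainUnet(ds$pairs, tinyTrainCfg(iterations = 80L))
  expect_lt(mean(tail(tr$loss, 10)), mean(head(tr$loss, 10)))
  expect_true(all(is.finite(tr$loss)))
  expect_s3_class(tr$log, "data.frame")
})

test_that("prediction methods honor their input contracts", {
  ds <- tinyDataset()
  tr <- trainUnet(ds$pairs, tinyTrainCfg(iterations = 10L))
  p <- ds$pairs[[1]]
  sr1 <- predictSR(tr, lrMap(p), method = "dl1")
  expect_identical(dim(sr1), dim(hrMap(p)))
  expect_gte(min(mapData(sr1)), 0)

  # dl2 with vanishing FNLM bandwidth equals dl1 where prior features are
  # distinct; on a strictly monotone prior surface it is the identity link
  surf <- outer(seq(0, 1, length.out = 32), seq(0, 1, length.out = 32),
                function(a, b) (a + 2 * b + a * b) / 4)
  pri <- priorImages(flair = surf)
  sr2 <- predictSR(tr, lrMap(p), prior = pri, method = "dl2", h = 1e-5)
  expect_lt(max(abs(mapData(sr2) - mapData(sr1))), 1e-6)

  expect_error(predictSR(tr, lrMap(p), method = "dl2"), "prior")
  expect_error(predictSR(tr, lrMap(p), prior = pri, method = "dl3"),
               "stacked prior")

  # two-input model: 1 + P channels
  cfg3 <- tinyTrainCfg(iterations = 5L)
  cfg3$generator$inChannels <- 3L
  tr3 <- trainUnet(ds$pairs, cfg3)
  sr3 <- predictSR(tr3, lrMap(p), prior = priorMaps(p), method = "dl3")
  expect_identical(dim(sr3), dim(hrMap(p)))
  expect_error(predictSR(tr3, lrMap(p), method = "dl1"), "single-input")
})

test_that("early stopping halts on a validation plateau", {
  ds <- tinyDataset()
  cfg <- tinyTrainCfg(iterations = 200L, lr = 0)   # no progress possible
  cfg$patience <- 2L
  cfg$logEvery <- 5L
  tr <- trainUnet(ds$pairs, cfg, validationPairs = ds$pairs[1:2])
  expect_lt(length(tr$loss), 200L)
})

test_that("GAN updates move both players and keep scores in (0, 1)", {
  ds <- tinyDataset()
  pre <- trainUnet(ds$pairs, tinyTrainCfg(iterations = 30L))
  dspec <- discriminatorSpec(inputSize = 32,
                             channels = c(4, 4, 8, 8, 16, 16, 32, 32),
                             denseWidth = 16, seed = 3)
  cfg <- tinyTrainCfg(iterations = 25L, lr = 1e-4)
  cfg$lambda <- 1e-3
  cfg$discriminator <- dspec
  gan <- trainGAN(ds$pairs, pre, cfg)
  expect_true(all(is.finite(gan$loss)))
  expect_true(all(gan$scoreReal > 0 & gan$scoreReal < 1))
  expect_true(all(gan$scoreFake > 0 & gan$scoreFake < 1))
  expect_false(identical(gan$model$params, pre$model$params))
  expect_false(identical(gan$discriminator$params,
                         buildDiscriminator(dspec)$params))

  # adversarial fine-tuning must not destroy fidelity on this toy set
  mseOf <- function(m) mean(vapply(ds$pairs, function(p)
    mean((mapData(predictSR(m, lrMap(p))) - mapData(hrMap(p)))^2), 0))
  expect_lte(mseOf(gan), mseOf(pre) * 1.10)
})

test_that("guard rails reject inconsistent GAN configurations", {
  ds <- tinyDataset()
  pre <- trainUnet(ds$pairs, tinyTrainCfg(iterations = 2L))
  cfg <- tinyTrainCfg(iterations = 2L)
  cfg$lambda <- 0
  expect_error(trainGAN(ds$pairs, pre, cfg), "lambda > 0")
  cfg$lambda <- 1e-3
  expect_error(trainGAN(ds$pairs, pre, cfg), "discriminator")
})
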