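test_that("PSNR follows its closed form and flags identity", {
  x <- matrix(runif(256), 16, 16)
  expect_identical(psnr(x, x), Inf)
  expect_equal(psnr(x, x + 0.1), 20, tolerance = 1e-10)  # 10 log10(1/0.01)

  set.seed(3)
  y <- matrix(runif(256), 16, 16)
  direct <- 10 * log10(1 / (sum((x - y)^2) / 256))       # independent MSE
  expect_equal(psnr(x, y), direct, tolerance = 1e-10)
  expect_equal(psnr(x, y), psnr(y, x))
  expect_error(psnr(x, y[1:8, 1:8]), "mismatch")
})

test_that("SSIM is 1 at identity, symmetric, and matches the sliding oracle", {
  set.seed(9)
  x <- matrix(runif(20 * 20), 20)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  for (rep in 1:20) {
    a <- matrix(runif(16 * 16), 16)
    b <- matrix(runif(16 * 16), 16)
    expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  }
  # textured image against its negative, brute-force windowed oracle
  y <- 1 - x
  expect_equal(ssim(x, y), oracleSSIM(x, y), tolerance = 1e-8)
  expect_error(ssim(x[1:8, 1:8], y[1:8, 1:8]), "window")
})

test_that("FSIM is maximal at identity and invariant to common scaling", {
  seg <- makeSegmentation(phantomConfig(seed = 17, tumorCount = 1))
  img <- mapData(composeVHR(seg, 0.5))
  expect_equal(fsim(img, img), 1, tolerance = 1e-12)

  blur <- fftUpsample(fftDownsample(img, 4), 4)
  s1 <- fsim(blur, img)
  s2 <- fsim(3.1 * blur, 3.1 * img)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("FSIM ranks a sharp reconstruction above a blurred one", {
  seg <- makeSegmentation(phantomConfig(seed = 23, tumorCount = 2))
  truth <- mapData(composeVHR(seg, 0.6))
  mild <- fftUpsample(fftDownsample(truth, 2), 2)
  heavy <- fftUpsample(fftDownsample(truth, 8), 8)
  expect_gt(fsim(mild, truth), fsim(heavy, truth))
})

test_that("constant image pairs give the declared degenerate FSIM", {
  expect_warning(s <- fsim(matrix(0.5, 32, 32), matrix(0.5, 32, 32)),
                 "degenerate")
  expect_equal(s, 1)
})

test_that("metrics degrade monotonically with increasing noise", {
  seg <- makeSegmentation(phantomConfig(seed = 31, tumorCount = 1))
  truth <- mapData(composeVHR(seg, 0.4))
  set.seed(14)
  ps <- ss <- numeric(5)
  for (k in 1:5) {
    noisy <- truth + matrix(rnorm(length(truth), sd = 0.01 * 2^(k - 1)),
                            nrow(truth))
    ps[k] <- psnr(noisy, truth)
    ss[k] <- ssim(noisy, truth)
  }
  expect_true(all(diff(ps) < 0))
  expect_true(all(diff(ss) < 0))
})

test_that("Mann-Whitney exact enumeration matches hand counts and wilcox.test", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_match(r$method, "exact")

  # cross-check against the independent implementation in stats
  set.seed(2)
  for (rep in 1:10) {
    a <- rnorm(5); b <- rnorm(6)
    ours <- mannWhitneyU(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }

  expect_equal(mannWhitneyU(rep(2, 4), rep(2, 5))$p, 1)
  expect_error(mannWhitneyU(numeric(0), 1), "nonempty")
})

test_that("the large-sample approximation agrees with a permutation oracle", {
  set.seed(8)
  a <- rnorm(30, 0.3); b <- rnorm(30)
  ours <- mannWhitneyU(a, b)
  pooled <- c(a, b)
  stat <- function(ix) sum(rank(pooled)[ix]) - 30 * 31 / 2
  obs <- stat(seq_len(30))
  mid <- 30 * 30 / 2
  perm <- replicate(1e5, stat(sample(60, 30)))
  pPerm <- min(1, 2 * min(mean(perm <= obs), mean(perm >= obs)))
  expect_lt(abs(ours$p - pPerm), 5e-3)
})

test_that("the U statistic is invariant under strictly monotone transforms", {
  set.seed(10)
  a <- runif(12); b <- runif(15)
  u0 <- mannWhitneyU(a, b)$U
  expect_equal(mannWhitneyU(exp(3 * a), exp(3 * b))$U, u0)
  expect_equal(mannWhitneyU(log(a + 1), log(b + 1))$U, u0)
})

test_that("method comparison reproduces group means and improvement identities", {
  # per-image values engineered to average to the reference group means
  mkvals <- function(m, n = 10) m + seq(-0.05, 0.05, length.out = n) * m / 10
  rows <- list()
  means <- list(bicubic = c(PSNR = 28.57, SSIM = 0.921, FSIM = 0.901),
                unet = c(PSNR = 33.10, SSIM = 0.964, FSIM = 0.964))
  for (meth in names(means))
    for (met in names(means[[meth]]))
      rows[[length(rows) + 1L]] <- data.frame(
        image = 1:10, method = meth, metric = met,
        value = mkvals(means[[meth]][[met]]))
  perImage <- do.call(rbind, rows)
  rep <- compareMethods(perImage, baseline = "bicubic")
  for (meth in names(means))
    for (met in names(means[[meth]])) {
      got <- rep@summary$mean[rep@summary$method == meth &
                                rep@summary$metric == met]
      expect_equal(got, unname(means[[meth]][[met]]), tolerance = 1e-9)
    }
  psnrImp <- rep@improvements$improvementPct[rep@improvements$metric == "PSNR"]
  expect_equal(psnrImp, 100 * (33.10 - 28.57) / 28.57, tolerance = 1e-9)

  # contender identical to baseline: zero improvement on every metric
  dup <- perImage[perImage$method == "bicubic", ]
  dup$method <- "copy"
  rep2 <- compareMethods(rbind(perImage[perImage$method == "bicubic", ], dup),
                         baseline = "bicubic")
  expect_true(all(abs(rep2@improvements$improvementPct) < 1e-12))
})

test_that("identically distributed methods rarely reach significance", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    v <- rnorm(16)
    w <- rnorm(16)
    perImage <- rbind(
      data.frame(image = 1:16, method = "a", metric = "PSNR", value = v),
      data.frame(image = 1:16, method = "b", metric = "PSNR", value = w))
    rep <- compareMethods(perImage, baseline = "a")
    hits <- hits + as.integer(rep@tests$significant[1])
  }
  expect_lte(hits, 2L)   # at alpha 0.05, >= 90% of seeds show no stars
})
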