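test_that("spectral-quality filtering masks exactly the failing voxels", {
  m <- matrix(runif(64), 8, 8)
  allpass <- spectralQualityFilter(m, matrix(1, 8, 8), threshold = 0)
  expect_identical(allpass$map, m)
  expect_true(all(allpass$mask))

  # threshold at the k-th smallest of distinct scores masks exactly k voxels
  set.seed(8)
  q <- matrix(sample(seq_len(64)) / 64, 8, 8)
  k <- ceiling(0.1 * 64)
  thr <- sort(q)[k]
  f <- spectralQualityFilter(m, q, thr)          # ties at threshold fail
  expect_equal(sum(!f$mask), k)
  expect_equal(sum(is.na(f$map)), k)

  expect_error(spectralQualityFilter(m, matrix(1, 4, 4), 0), "aligned")
})

test_that("harmonic inpainting solves the discrete Laplace problem", {
  m <- matrix(0.7, 9, 9)
  expect_identical(inpaintMissing(m), m)         # nothing missing

  m1 <- m; m1[5, 5] <- NA
  expect_lt(abs(inpaintMissing(m1)[5, 5] - 0.7), 1e-6)

  # missing voxel inside a linear ramp: the harmonic fill is the ramp value
  ramp <- outer(seq(0, 1, length.out = 9), rep(1, 9))
  r1 <- ramp; r1[4, 6] <- NA
  expect_lt(abs(inpaintMissing(r1)[4, 6] - ramp[4, 6]), 1e-3)

  # direct sparse Laplace solve as oracle for a missing block
  rb <- ramp
  miss <- cbind(c(4, 4, 5), c(4, 5, 4))
  rb[miss] <- NA
  filled <- inpaintMissing(rb, tol = 1e-9)
  idx <- which(is.na(rb))
  A <- diag(length(idx))
  bvec <- numeric(length(idx))
  H <- nrow(rb)
  for (q in seq_along(idx)) {
    i <- (idx[q] - 1) %% H + 1; j <- (idx[q] - 1) %/% H + 1
    nbrs <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    nbrs <- nbrs[nbrs[, 1] >= 1 & nbrs[, 1] <= H &
                   nbrs[, 2] >= 1 & nbrs[, 2] <= ncol(rb), , drop = FALSE]
    for (r in seq_len(nrow(nbrs))) {
      lin <- nbrs[r, 1] + H * (nbrs[r, 2] - 1)
      if (lin %in% idx) A[q, match(lin, idx)] <- A[q, match(lin, idx)] -
          1 / nrow(nbrs)
      else bvec[q] <- bvec[q] + ramp[lin] / nrow(nbrs)
    }
  }
  exact <- solve(A, bvec)
  expect_lt(max(abs(filled[idx] - exact)), 1e-5)

  allNA <- matrix(NA_real_, 4, 4)
  expect_error(inpaintMissing(allNA), "missing")
})

test_that("NLM denoising preserves constants, approaches identity as h -> 0", {
  const <- matrix(0.4, 16, 16)
  expect_lt(max(abs(nlmDenoise(const, h = 0.3) - const)), 1e-12)

  set.seed(6)
  x <- matrix(runif(16 * 16), 16)
  near <- nlmDenoise(x, h = 1e-4)
  expect_lt(max(abs(near - x)), 1e-3)
  expect_error(nlmDenoise(x, h = 0), "> 0")
})

test_that("NLM reduces noise on piecewise-constant images and keeps the mean", {
  clean <- matrix(0.2, 32, 32)
  clean[9:24, 9:24] <- 0.8
  set.seed(12)
  noisy <- clean + matrix(rnorm(32 * 32, sd = 0.05), 32)
  den <- nlmDenoise(noisy, h = 0.1)
  expect_lt(stats::sd(den - clean), stats::sd(noisy - clean))
  expect_lt(abs(mean(den) - mean(noisy)) / mean(noisy), 0.01)
})

test_that("the all-pass conditioning chain reduces to NLM denoising alone", {
  set.seed(3)
  m <- matrix(runif(64), 8, 8)
  chain <- preprocessLR(m, quality = matrix(1, 8, 8), threshold = 0, h = 0.1)
  expect_identical(chain$map, nlmDenoise(m, h = 0.1))
  expect_true(all(chain$mask))
})

test_that("ratio maps follow their defining formulas and flag bad denominators", {
  mk <- function(v) matrix(v, 2, 2)
  maps <- list(`2hg` = mk(0.1), gln = mk(0.1), glu = mk(0.2),
               tcho = mk(0.2), tnaa = mk(1.0))
  r <- computeRatioMaps(maps)
  expect_equal(r$HGG[1, 1], 1.0)       # (0.1 + 0.1) / 0.2
  expect_equal(r$TCN[1, 1], 0.2)       # 0.2 / 1.0

  maps$glu[2, 2] <- 0
  r2 <- computeRatioMaps(maps, ratios = "HGG")
  expect_true(is.na(r2$HGG[2, 2]))
  expect_false(any(is.infinite(r2$HGG)))

  # scale invariance: common scaling of all metabolite maps cancels
  scaled <- lapply(maps, function(m) 3.7 * m)
  r3 <- computeRatioMaps(scaled)
  expect_equal(r3$HGG[1, 1], r$HGG[1, 1], tolerance = 1e-12)
  expect_equal(r3$TCN[1, 1], r$TCN[1, 1], tolerance = 1e-12)

  expect_error(computeRatioMaps(list(gln = mk(1), glu = mk(1)),
                                ratios = "HGG"), "missing required")
})
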