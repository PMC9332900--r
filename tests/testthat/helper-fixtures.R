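# Shared fixtures, built in code. Tiny grids (32x32 VHR, 8x8 LR) keep the
# unit tests fast; the acceptance suite uses the full desk-scale setup.

tinyConfig <- function(seed = 1L, ...)
  phantomConfig(gridDim = c(32L, 32L), tumorCount = 1L,
                tumorRadius = c(3, 6), seed = seed, ...)

# memoized tiny dataset shared across test files
.fixtureEnv <- new.env()

tinyDataset <- function(n = 8L, seed = 11L) {
  key <- sprintf("ds_%d_%d", n, seed)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- generateDataset(n, tinyConfig(seed), seed = seed,
                                          withPrior = TRUE,
                                          validationFraction = 0)
  .fixtureEnv[[key]]
}

# centered disk phantom (piecewise constant, strong ringing under truncation)
diskImage <- function(n = 64, radius = n / 4, value = 1) {
  ctr <- (n + 1) / 2
  d <- outer(seq_len(n), seq_len(n),
             function(i, j) sqrt((i - ctr)^2 + (j - ctr)^2))
  (d <= radius) * value
}

# hand-built segmentation with pure-tissue voxels for composition checks
pureSegmentation <- function() {
  z <- array(0, c(8, 8))
  gm <- z; wm <- z; csf <- z; tm <- z
  gm[2, 2] <- 1; wm[3, 3] <- 1; csf[4, 4] <- 1; tm[5, 5] <- 1
  gm[6, 6] <- 0.5; wm[6, 6] <- 0.5
  new("TissueSegmentation", gm = gm, wm = wm, csf = csf, tm = tm,
      voxelSize = c(1, 1))
}

# independent DFT-truncation oracle: explicit DFT matrices, same band-edge
# convention (fold on truncation), no stats::fft anywhere.
dftMatrix <- function(n)
  outer(0:(n - 1), 0:(n - 1), function(j, k) exp(-2i * pi * j * k / n))

oracleFftDownsample <- function(x, factor) {
  N1 <- nrow(x); N2 <- ncol(x)
  M1 <- N1 / factor; M2 <- N2 / factor
  X <- dftMatrix(N1) %*% x %*% t(dftMatrix(N2))
  sel <- function(N, M) {
    # signed frequencies -M/2 .. M/2-1 plus the folded +M/2 alias
    k <- seq.int(-M %/% 2, M %/% 2 - 1)
    Tm <- matrix(0, M, N)
    Tm[cbind((k %% M) + 1, (k %% N) + 1)] <- 1
    if (M %% 2 == 0) {
      Tm[((-M %/% 2) %% M) + 1, ((M %/% 2) %% N) + 1] <-
        Tm[((-M %/% 2) %% M) + 1, ((M %/% 2) %% N) + 1] + 1
    }
    Tm
  }
  Y <- sel(N1, M1) %*% X %*% t(sel(N2, M2))
  Re(Conj(dftMatrix(M1)) %*% Y %*% t(Conj(dftMatrix(M2)))) / (N1 * N2)
}

# brute-force sliding-window SSIM oracle: explicit loops over window
# positions, statistics computed from scratch each window.
oracleSSIM <- function(x, y, dataRange = 1, windowSize = 11,
                       windowSigma = 1.5, K = c(0.01, 0.03)) {
  r <- (windowSize - 1) / 2
  k1 <- exp(-(seq(-r, r))^2 / (2 * windowSigma^2))
  k1 <- k1 / sum(k1)
  w <- outer(k1, k1)
  C1 <- (K[1] * dataRange)^2; C2 <- (K[2] * dataRange)^2
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (i in seq_len(H - windowSize + 1)) {
    for (j in seq_len(W - windowSize + 1)) {
      px <- x[i:(i + windowSize - 1), j:(j + windowSize - 1)]
      py <- y[i:(i + windowSize - 1), j:(j + windowSize - 1)]
      mx <- sum(w * px); my <- sum(w * py)
      vx <- sum(w * px^2) - mx^2; vy <- sum(w * py^2) - my^2
      cxy <- sum(w * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}
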