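## Full-reference image quality metrics (PSNR, SSIM, FSIM) and the
## nonparametric group statistics used to compare upsampling methods.

.metricCheck <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("image shape mismatch")
}

.sliceApply <- function(x, y, f, ...) {
  # 3D volumes are scored slice-wise and averaged
  if (length(dim(x)) == 3L) {
    mean(vapply(seq_len(dim(x)[3]),
                function(k) f(x[, , k], y[, , k], ...), 0))
  } else f(x, y, ...)
}

#' Peak signal-to-noise ratio
#'
#' \code{10 log10(dataRange^2 / MSE)} in dB. Identical images return
#' \code{Inf}.
#'
#' @param x,y maps or arrays of the same shape.
#' @param dataRange intensity range of the data (default 1 for normalized
#'   metabolite maps).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, dataRange = 1) {
  if (dataRange <= 0) stop("'dataRange' must be > 0")
  x <- .asArr(x); y <- .asArr(y)
  .metricCheck(x, y)
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(dataRange^2 / mse)
}

# separable "valid" correlation with a 1D kernel along both axes
.filter2valid <- function(x, k) {
  n <- length(k)
  H <- nrow(x); W <- ncol(x)
  Kr <- matrix(0, H - n + 1L, H)
  for (i in seq_len(H - n + 1L)) Kr[i, i:(i + n - 1L)] <- k
  Kc <- matrix(0, W - n + 1L, W)
  for (j in seq_len(W - n + 1L)) Kc[j, j:(j + n - 1L)] <- k
  Kr %*% x %*% t(Kc)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with a Gaussian window (sigma 1.5, 11x11 by default) and
#' stabilizers \code{C1 = (K1 dataRange)^2}, \code{C2 = (K2 dataRange)^2},
#' K1 = 0.01, K2 = 0.03. Local statistics are taken over fully interior
#' windows ("valid" filtering). 3D inputs are scored slice-wise.
#'
#' @inheritParams psnr
#' @param windowSize odd window width in voxels.
#' @param windowSigma Gaussian window standard deviation.
#' @param K the two stabilizer constants.
#' @return mean SSIM in [-1, 1].
#' @export
ssim <- function(x, y, dataRange = 1, windowSize = 11L, windowSigma = 1.5,
                 K = c(0.01, 0.03)) {
  x <- .asArr(x); y <- .asArr(y)
  .metricCheck(x, y)
  .sliceApply(x, y, function(a, b) {
    if (windowSize > min(dim(a)))
      stop("SSIM window larger than the image")
    r <- (windowSize - 1) / 2
    k <- exp(-(seq(-r, r))^2 / (2 * windowSigma^2))
    k <- k / sum(k)
    C1 <- (K[1] * dataRange)^2
    C2 <- (K[2] * dataRange)^2
    mx <- .filter2valid(a, k); my <- .filter2valid(b, k)
    sxx <- .filter2valid(a * a, k) - mx^2
    syy <- .filter2valid(b * b, k) - my^2
    sxy <- .filter2valid(a * b, k) - mx * my
    s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
      ((mx^2 + my^2 + C1) * (sxx + syy + C2))
    mean(s)
  })
}

# ---- FSIM -------------------------------------------------------------

# Log-Gabor spread filters in the frequency domain (Kovesi construction):
# 4 scales (min wavelength 6, multiplier 2, sigmaOnf 0.55) by 4
# orientations (Gaussian angular spread, dThetaOnSigma 1.2), with a
# low-pass guard. Returns a list[orient][scale] of H x W transfer matrices.
.logGaborBank <- function(H, W, nscale = 4L, norient = 4L,
                          minWaveLength = 6, mult = 2, sigmaOnf = 0.55,
                          dThetaOnSigma = 1.2) {
  fx <- ifelse(seq_len(W) - 1 <= W / 2, seq_len(W) - 1, seq_len(W) - 1 - W) / W
  fy <- ifelse(seq_len(H) - 1 <= H / 2, seq_len(H) - 1, seq_len(H) - 1 - H) / H
  u <- matrix(fx, H, W, byrow = TRUE)
  v <- matrix(fy, H, W)
  radius <- sqrt(u^2 + v^2)
  radius[1, 1] <- 1
  theta <- atan2(-v, u)
  lp <- 1 / (1 + (radius / 0.45)^(2 * 15))    # Butterworth low-pass guard
  sigmaTheta <- (pi / norient) / dThetaOnSigma
  lapply(seq_len(norient), function(o) {
    ang <- (o - 1) * pi / norient
    ds <- sin(theta) * cos(ang) - cos(theta) * sin(ang)
    dc <- cos(theta) * cos(ang) + sin(theta) * sin(ang)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * sigmaTheta^2))
    lapply(seq_len(nscale), function(s) {
      wl <- minWaveLength * mult^(s - 1)
      f0 <- 1 / wl
      lg <- exp(-(log(radius / f0))^2 / (2 * log(sigmaOnf)^2)) * lp
      lg[1, 1] <- 0
      lg * spread
    })
  })
}

# Phase congruency map (Kovesi's PC2 with noise compensation, k = 2).
.phaseCongruency <- function(im, bank, nscale = 4L, mult = 2) {
  H <- nrow(im); W <- ncol(im)
  IM <- stats::fft(im)
  epsl <- 1e-4
  energyAll <- matrix(0, H, W)
  anAll <- matrix(0, H, W)
  for (filts in bank) {
    sumE <- sumO <- sumAn <- matrix(0, H, W)
    an1 <- NULL
    for (s in seq_along(filts)) {
      eo <- stats::fft(IM * filts[[s]], inverse = TRUE) / (H * W)
      e <- Re(eo); o <- Im(eo)
      an <- sqrt(e^2 + o^2)
      if (s == 1L) an1 <- an
      sumE <- sumE + e; sumO <- sumO + o; sumAn <- sumAn + an
    }
    xE <- sqrt(sumE^2 + sumO^2) + epsl
    mE <- sumE / xE; mO <- sumO / xE
    energy <- matrix(0, H, W)
    for (s in seq_along(filts)) {
      eo <- stats::fft(IM * filts[[s]], inverse = TRUE) / (H * W)
      e <- Re(eo); o <- Im(eo)
      energy <- energy + e * mE + o * mO - abs(e * mO - o * mE)
    }
    tau <- stats::median(an1) / sqrt(log(4))
    totalTau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    noiseMean <- totalTau * sqrt(pi / 2)
    noiseSigma <- totalTau * sqrt((4 - pi) / 2)
    Tthr <- noiseMean + 2 * noiseSigma
    energyAll <- energyAll + pmax(energy - Tthr, 0)
    anAll <- anAll + sumAn
  }
  energyAll / (anAll + epsl)
}

# Scharr gradient magnitude
.scharrMag <- function(im) {
  kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3, byrow = TRUE) / 16
  pad <- function(m) {
    m <- rbind(m[1, ], m, m[nrow(m), ])
    cbind(m[, 1], m, m[, ncol(m)])
  }
  xp <- pad(im)
  H <- nrow(im); W <- ncol(im)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  for (a in 1:3) for (b in 1:3) {
    sub <- xp[a:(a + H - 1), b:(b + W - 1)]
    gx <- gx + kx[a, b] * sub
    gy <- gy + kx[b, a] * sub
  }
  sqrt(gx^2 + gy^2)
}

#' Feature similarity index (FSIM)
#'
#' Combines phase-congruency similarity and gradient-magnitude (Scharr)
#' similarity, pooled with max-phase-congruency weighting, following the
#' metric's standard definition (log-Gabor phase congruency, 4
#' scales x 4 orientations; T1 = 0.85, T2 = 160 on a 0-255 intensity
#' scale). Inputs are rescaled to 0-255 by the joint data range, which
#' makes the score invariant to a common global intensity scaling. Large
#' images are average-pooled by \code{round(min(dim)/256)} first. 3D inputs
#' are scored slice-wise. Constant (feature-free) image pairs are degenerate
#' and return 1 with a warning.
#'
#' @inheritParams psnr
#' @param dataRange intensity range; \code{NULL} (default) uses the joint
#'   maximum of both images.
#' @return FSIM in [0, 1].
#' @export
fsim <- function(x, y, dataRange = NULL) {
  x <- .asArr(x); y <- .asArr(y)
  .metricCheck(x, y)
  .sliceApply(x, y, function(a, b) {
    rng <- if (is.null(dataRange)) max(a, b) - min(0, min(a, b)) else dataRange
    if (rng <= 0) {
      warning("constant images: FSIM is degenerate, returning 1")
      return(1)
    }
    a <- a * (255 / rng); b <- b * (255 / rng)
    f <- max(1, round(min(dim(a)) / 256))
    if (f > 1) {
      pool <- function(m) {
        H <- (nrow(m) %/% f) * f; W <- (ncol(m) %/% f) * f
        m <- m[seq_len(H), seq_len(W)]
        ar <- array(m, dim = c(f, H / f, f, W / f))
        apply(ar, c(2, 4), mean)
      }
      a <- pool(a); b <- pool(b)
    }
    bank <- .logGaborBank(nrow(a), ncol(a))
    pc1 <- .phaseCongruency(a, bank)
    pc2 <- .phaseCongruency(b, bank)
    if (max(pc1) == 0 && max(pc2) == 0) {
      warning("no phase congruency detected: FSIM is degenerate, returning 1")
      return(1)
    }
    g1 <- .scharrMag(a); g2 <- .scharrMag(b)
    T1 <- 0.85; T2 <- 160
    sPC <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
    sG <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
    pcm <- pmax(pc1, pc2)
    sum(sPC * sG * pcm) / sum(pcm)
  })
}

# ---- Mann-Whitney U ---------------------------------------------------

#' Mann-Whitney U test
#'
#' Rank-sum test for a difference between two independent samples. For
#' \code{length(a) + length(b) <= 12} the two-sided p-value is computed by
#' exact enumeration of all group assignments; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' With all pooled values tied the p-value is 1.
#'
#' @param a,b numeric samples (each nonempty).
#' @return list with \code{U} (the U statistic of sample \code{a}),
#'   \code{p} (two-sided), and \code{method} used.
#' @export
mannWhitneyU <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p = 1, method = "degenerate (all tied)"))
  if (na + nb <= 12L) {
    combos <- utils::combn(na + nb, na)
    Us <- apply(combos, 2, function(ix) sum(rk[ix]) - na * (na + 1) / 2)
    mid <- na * nb / 2
    p <- min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9)))
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  ties <- table(pooled)
  n <- na + nb
  mu <- na * nb / 2
  sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(U = U, p = 1, method = "degenerate (all tied)"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  list(U = U, p = 2 * stats::pnorm(-abs(z)),
       method = "normal approximation with tie correction")
}

# ---- group comparison -------------------------------------------------

#' Evaluate SR outputs against ground truth
#'
#' Computes PSNR, SSIM and FSIM for each (truth, prediction) pair of each
#' method and stacks them in the long per-image format consumed by
#' [compareMethods()].
#'
#' @param truths list of ground-truth maps/arrays.
#' @param predictions named list (one entry per method) of lists of
#'   predictions aligned with \code{truths}.
#' @param dataRange PSNR/SSIM data range.
#' @param mask optional logical array restricting PSNR to a brain mask
#'   (SSIM/FSIM stay full-image; windowed metrics need the full lattice).
#' @return data.frame with columns image, method, metric, value.
#' @export
evaluateSR <- function(truths, predictions, dataRange = 1, mask = NULL) {
  rows <- list()
  for (meth in names(predictions)) {
    preds <- predictions[[meth]]
    stopifnot(length(preds) == length(truths))
    for (i in seq_along(truths)) {
      tr <- .asArr(truths[[i]]); pr <- .asArr(preds[[i]])
      if (!is.null(mask)) {
        p <- psnr(tr[mask], pr[mask], dataRange)
      } else p <- psnr(tr, pr, dataRange)
      rows[[length(rows) + 1L]] <- data.frame(
        image = i, method = meth,
        metric = c("PSNR", "SSIM", "FSIM"),
        value = c(p, ssim(pr, tr, dataRange), fsim(pr, tr)))
    }
  }
  do.call(rbind, rows)
}

#' Compare upsampling methods on shared images
#'
#' Summarizes per-image metrics into group means, percent improvement of
#' each contender over the baseline (computed on group means, with the
#' per-image paired improvement mean also reported), and Mann-Whitney U
#' tests per metric. Significance stars mark p < 0.05.
#'
#' @param perImage data.frame from [evaluateSR()] (columns image, method,
#'   metric, value).
#' @param baseline baseline method name.
#' @param contenders methods compared against the baseline (default: all
#'   others present).
#' @return a \linkS4class{MetricReport}.
#' @export
compareMethods <- function(perImage, baseline,
                           contenders = setdiff(unique(perImage$method),
                                                baseline)) {
  stopifnot(baseline %in% perImage$method)
  imgSets <- tapply(perImage$image, perImage$method,
                    function(v) paste(sort(unique(v)), collapse = ","))
  if (length(unique(imgSets[c(baseline, contenders)])) != 1L)
    stop("methods were not evaluated on the same image set")
  finite <- perImage
  finite$value[!is.finite(finite$value)] <- NA
  summary <- stats::aggregate(value ~ method + metric, finite, mean,
                              na.rm = TRUE)
  names(summary)[names(summary) == "value"] <- "mean"
  imp <- list(); tst <- list()
  for (met in unique(perImage$metric)) {
    base <- finite[finite$method == baseline & finite$metric == met, ]
    base <- base[order(base$image), ]
    for (ct in contenders) {
      cont <- finite[finite$method == ct & finite$metric == met, ]
      cont <- cont[order(cont$image), ]
      mb <- mean(base$value, na.rm = TRUE)
      mc <- mean(cont$value, na.rm = TRUE)
      pairedImp <- 100 * mean((cont$value - base$value) / base$value,
                              na.rm = TRUE)
      imp[[length(imp) + 1L]] <- data.frame(
        metric = met, method = ct, baselineMean = mb, mean = mc,
        improvementPct = 100 * (mc - mb) / mb,
        pairedImprovementPct = pairedImp)
      mw <- mannWhitneyU(cont$value[!is.na(cont$value)],
                         base$value[!is.na(base$value)])
      tst[[length(tst) + 1L]] <- data.frame(
        metric = met, method = ct, U = mw$U, p = mw$p,
        significant = mw$p < 0.05, test = mw$method)
    }
  }
  new("MetricReport", perImage = perImage, summary = summary,
      tests = do.call(rbind, tst), improvements = do.call(rbind, imp),
      baseline = baseline)
}
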