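## Procedural brain phantom simulation: synthetic GM/WM/CSF/tumor
## segmentations composed into metabolic maps, plus the LR/HR training-pair
## factory implementing the x4 k-space degradation recipe.

#' The discrete tumor-weight grid
#'
#' Tumor compartment weights tau used when composing metabolic maps:
#' 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8.
#' @export
tauGrid <- function() seq(0.2, 0.8, by = 0.1)

.TISSUE_WEIGHTS <- c(gm = 0.10, wm = 0.12, csf = 0.0)

# Evaluate expr under a fixed seed, restoring the caller's RNG stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Separable Gaussian blur with zero extension; kernel normalized to sum 1,
# so blurring a partition of unity keeps per-voxel sums <= 1.
.gaussBlur2d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(n) {
    K <- matrix(0, n, n)
    for (d in seq(-r, r)) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[d + r + 1]
    }
    K
  }
  blur1(nrow(x)) %*% x %*% t(blur1(ncol(x)))
}

#' Phantom simulation configuration
#'
#' Parameters of the procedural tissue phantom: a deformed-ellipse head with
#' a CSF rim, a folded cortical gray-matter ribbon, white-matter core,
#' ventricles, and 0-N tumor blobs. Defaults target the desk-scale grid
#' (128x128 slices, x4 LR-HR factor); the full-scale 3D grids are reachable
#' through \code{gridDim}.
#'
#' @param gridDim integer vector, VHR grid (default \code{c(128, 128)}).
#' @param voxelSize VHR voxel size in mm (default 1.3, the HR voxel size of
#'   a 5.2 mm acquisition upsampled x4).
#' @param factor LR-HR downsampling factor (each \code{gridDim} axis must be
#'   divisible by it).
#' @param tumorCount number of tumor blobs; \code{NULL} samples 0-2 per
#'   phantom.
#' @param tumorRadius range (voxels) of tumor semi-axes.
#' @param boundaryRoughness relative amplitude of the low-order angular
#'   perturbation of the head boundary.
#' @param sulcalAmplitude amplitude of the higher-frequency folding of the
#'   GM/WM interface (sulcus-like).
#' @param pvBlurSigma partial-volume blur of the hard labels, in VHR voxels.
#' @param noiseStd additive Gaussian noise applied to simulated LR maps
#'   (degradation-model noise term; the composition recipe itself is
#'   noise-free, so the default is 0).
#' @param seed integer seed making the phantom deterministic.
#' @return a classed list of validated parameters.
#' @export
phantomConfig <- function(gridDim = c(128L, 128L), voxelSize = 1.3,
                          factor = 4L, tumorCount = NULL,
                          tumorRadius = c(6, 14), boundaryRoughness = 0.05,
                          sulcalAmplitude = 0.045, pvBlurSigma = 1,
                          noiseStd = 0, seed = 1L) {
  gridDim <- as.integer(gridDim)
  if (length(gridDim) != 2L)
    stop("phantom simulation generates 2D slices; 'gridDim' must be length 2")
  if (any(gridDim %% as.integer(factor) != 0L))
    stop(sprintf("grid (%s) not divisible by the downsampling factor %d",
                 paste(gridDim, collapse = "x"), as.integer(factor)))
  if (!is.null(tumorCount) && tumorCount < 0) stop("'tumorCount' must be >= 0")
  structure(list(gridDim = gridDim,
                 voxelSize = rep_len(as.numeric(voxelSize), 2L),
                 factor = as.integer(factor), tumorCount = tumorCount,
                 tumorRadius = tumorRadius,
                 boundaryRoughness = boundaryRoughness,
                 sulcalAmplitude = sulcalAmplitude,
                 pvBlurSigma = pvBlurSigma, noiseStd = noiseStd,
                 seed = as.integer(seed)),
            class = "PhantomConfig")
}

# Inside-ellipse indicator with angular boundary perturbation.
.blobMask <- function(X, Y, center, semi, angle, pert) {
  u <- cos(angle) * (X - center[1]) + sin(angle) * (Y - center[2])
  v <- -sin(angle) * (X - center[1]) + cos(angle) * (Y - center[2])
  rho <- sqrt((u / semi[1])^2 + (v / semi[2])^2)
  theta <- atan2(v, u)
  mod <- rep(1, length(theta))
  if (length(pert$k))
    for (q in seq_along(pert$k))
      mod <- mod + pert$a[q] * cos(pert$k[q] * theta + pert$phi[q])
  rho <= pmax(mod, 0.5)
}

#' Generate a synthetic tissue segmentation
#'
#' Draws a brain-like 2D phantom: head outline (deformed ellipse), thin CSF
#' rim, cortical GM ribbon with sulcal-like folds, WM interior, ventricular
#' CSF, and tumor blobs placed in the deep white matter. Hard labels receive
#' a small Gaussian partial-volume blur so compartment boundaries carry
#' fractional tissue content. Deterministic given \code{config$seed}.
#'
#' @param config a [phantomConfig()].
#' @return a \linkS4class{TissueSegmentation}.
#' @examples
#' seg <- makeSegmentation(phantomConfig(seed = 7))
#' range(mapData(seg)$gm)
#' @export
makeSegmentation <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  .withSeed(config$seed, {
    H <- config$gridDim[1]; W <- config$gridDim[2]
    X <- matrix(seq_len(H), H, W)
    Y <- matrix(seq_len(W), H, W, byrow = TRUE)
    ctr <- c(H, W) / 2 + stats::runif(2, -2, 2)
    semi <- c(0.42 * H, 0.36 * W) * stats::runif(2, 0.95, 1.05)
    ang <- stats::runif(1, 0, pi)
    u <- cos(ang) * (X - ctr[1]) + sin(ang) * (Y - ctr[2])
    v <- -sin(ang) * (X - ctr[1]) + cos(ang) * (Y - ctr[2])
    theta <- atan2(v, u)
    kk <- 2:5
    aa <- stats::rnorm(length(kk), 0, config$boundaryRoughness / sqrt(kk))
    ph <- stats::runif(length(kk), 0, 2 * pi)
    bmod <- 1
    for (q in seq_along(kk)) bmod <- bmod + aa[q] * cos(kk[q] * theta + ph[q])
    rho <- sqrt((u / semi[1])^2 + (v / semi[2])^2) / pmax(bmod, 0.5)

    # sulcal folding of the GM/WM interface
    ks <- sample(7:13, 3)
    as <- stats::runif(3, 0.5, 1) * config$sulcalAmplitude
    phs <- stats::runif(3, 0, 2 * pi)
    fold <- as[1] * cos(ks[1] * theta + phs[1]) +
      as[2] * cos(ks[2] * theta + phs[2]) +
      as[3] * cos(ks[3] * theta + phs[3])
    gmInner <- 0.74 + fold

    lab <- matrix(0L, H, W)          # 0 bg, 1 gm, 2 wm, 3 csf, 4 tm
    lab[rho <= 1] <- 3L              # outer CSF rim
    lab[rho <= 0.93] <- 1L           # cortical GM
    lab[rho <= gmInner] <- 2L        # WM core

    # ventricles: two mirrored CSF blobs near the center
    for (s in c(-1, 1)) {
      vc <- ctr + c(stats::runif(1, -0.02, 0.02) * H,
                    s * stats::runif(1, 0.07, 0.10) * W)
      vmask <- .blobMask(X, Y, vc, c(0.11 * H, 0.045 * W) *
                           stats::runif(2, 0.85, 1.15),
                         ang + stats::runif(1, -0.3, 0.3),
                         list(k = 2:3, a = stats::rnorm(2, 0, 0.06),
                              phi = stats::runif(2, 0, 2 * pi)))
      lab[vmask & lab == 2L] <- 3L
    }

    nTum <- if (is.null(config$tumorCount)) sample(0:2, 1)
            else as.integer(config$tumorCount)
    if (nTum > 0) {
      deep <- which(rho <= 0.6 & lab == 2L)
      for (t in seq_len(nTum)) {
        if (!length(deep)) break
        pick <- deep[sample.int(length(deep), 1)]
        tc <- c((pick - 1) %% H + 1, (pick - 1) %/% H + 1)
        tr <- stats::runif(2, config$tumorRadius[1], config$tumorRadius[2])
        tmask <- .blobMask(X, Y, tc, tr, stats::runif(1, 0, pi),
                           list(k = 2:4, a = stats::rnorm(3, 0, 0.08),
                                phi = stats::runif(3, 0, 2 * pi)))
        lab[tmask & lab != 0L] <- 4L
      }
    }

    frac <- lapply(1:4, function(l)
      .gaussBlur2d((lab == l) * 1, config$pvBlurSigma))
    new("TissueSegmentation", gm = as.array(frac[[1]]),
        wm = as.array(frac[[2]]), csf = as.array(frac[[3]]),
        tm = as.array(frac[[4]]), voxelSize = config$voxelSize)
  })
}

#' Compose a very-high-resolution metabolic map from tissue fractions
#'
#' Voxel values are the fixed-weight tissue mixture
#' \code{0.1*GM + 0.12*WM + 0*CSF + tau*TM}, after which the whole map is
#' divided by its maximum so the intensity range is [0, 1].
#'
#' @param seg a \linkS4class{TissueSegmentation}.
#' @param tau tumor weight, one of [tauGrid()].
#' @param normalize divide by the map maximum (default TRUE). With an
#'   all-zero segmentation normalization is skipped and an all-zero map is
#'   returned with a warning.
#' @return a \linkS4class{MetabolicMap} with tier \code{"VHR"}.
#' @export
composeVHR <- function(seg, tau, normalize = TRUE) {
  stopifnot(is(seg, "TissueSegmentation"))
  if (!any(abs(tau - tauGrid()) < 1e-9))
    stop("'tau' must be one of the allowed grid: ",
         paste(tauGrid(), collapse = ", "))
  w <- .TISSUE_WEIGHTS
  m <- w["gm"] * seg@gm + w["wm"] * seg@wm + w["csf"] * seg@csf + tau * seg@tm
  if (normalize) {
    mx <- max(m)
    if (mx == 0) warning("all-zero composed map; normalization skipped")
    else m <- m / mx
  }
  MetabolicMap(m, voxelSize = seg@voxelSize, tier = "VHR")
}

#' Synthetic anatomical prior contrasts for a phantom
#'
#' Builds FLAIR-like and MPRAGE-like anatomical images from the same tissue
#' fractions, with contrast weights chosen to mimic the respective tissue
#' appearance (CSF dark on both, tumor bright on FLAIR, WM bright on
#' MPRAGE). These stand in for measured co-registered anatomical MRI and
#' are normalized to [0, 1].
#'
#' @param seg a \linkS4class{TissueSegmentation}.
#' @return a \linkS4class{PriorImages} with elements \code{flair} and
#'   \code{mprage} on the segmentation grid.
#' @export
makePriorImages <- function(seg) {
  stopifnot(is(seg, "TissueSegmentation"))
  mk <- function(wgts) {
    m <- wgts[1] * seg@gm + wgts[2] * seg@wm + wgts[3] * seg@csf +
      wgts[4] * seg@tm
    mx <- max(m)
    MetabolicMap(if (mx > 0) m / mx else m, voxelSize = seg@voxelSize,
                 tier = "HR")
  }
  priorImages(flair = mk(c(0.55, 0.32, 0.08, 0.95)),
              mprage = mk(c(0.60, 0.88, 0.10, 0.35)))
}

#' Generate the high-resolution ground truth for a training pair
#'
#' Two ground-truth modes are supported: \code{"kspace_sharp"} truncates
#' the VHR map in k-space to the HR grid (sharp structural detail with mild
#' ringing), while \code{"fnlm_smooth"} upsamples the LR map with the
#' classical FNLM pipeline guided by anatomical priors (smoother edges,
#' resembling maps from advanced high-resolution acquisitions).
#'
#' @param vhr the VHR \linkS4class{MetabolicMap}.
#' @param mode \code{"kspace_sharp"} or \code{"fnlm_smooth"}.
#' @param targetDim HR grid (defaults to the VHR grid, i.e. identity
#'   truncation at desk scale; use e.g. \code{c(184, 184)} for full-scale).
#' @param lr LR map, required for \code{"fnlm_smooth"}.
#' @param prior \linkS4class{PriorImages} on the HR grid, required for
#'   \code{"fnlm_smooth"}.
#' @param h FNLM similarity bandwidth for the smooth mode.
#' @return a \linkS4class{MetabolicMap} with tier \code{"HR"}.
#' @export
makeHRTruth <- function(vhr, mode = c("kspace_sharp", "fnlm_smooth"),
                        targetDim = dim(vhr), lr = NULL, prior = NULL,
                        h = 0.1) {
  mode <- match.arg(mode)
  if (mode == "kspace_sharp")
    return(fftResample(vhr, targetDim, tier = "HR"))
  if (is.null(prior))
    stop("'fnlm_smooth' ground truth requires prior anatomical images")
  if (is.null(lr)) stop("'fnlm_smooth' ground truth requires the LR map")
  fac <- unique(as.integer(targetDim %/% dim(lr@data)))
  isr <- bicubicUpsample(lr, fac[1])
  out <- fnlmReinterpolate(isr, prior, h = h)
  out@tier <- "HR"
  out
}

#' Flip/crop augmentation of a training pair
#'
#' Applies a random flip per axis (probability 0.5 each) and an aligned
#' random crop: the crop origin is drawn on the LR grid and the HR (and
#' prior) crop origin is \code{factor} times it, so LR/HR stay consistent
#' under the degradation model up to a boundary band. Uses the current R
#' random stream.
#'
#' @param pair a \linkS4class{TrainingPair}.
#' @param cropSize crop size in LR voxels (scalar); \code{NULL} keeps the
#'   full field of view.
#' @param flip apply random flips (set \code{FALSE} to disable).
#' @return the augmented \linkS4class{TrainingPair}.
#' @export
augmentPair <- function(pair, cropSize = NULL, flip = TRUE) {
  stopifnot(is(pair, "TrainingPair"))
  lr <- pair@lr@data; hr <- pair@hr@data
  fac <- dim(hr)[1] %/% dim(lr)[1]
  pri <- priorMaps(pair)
  flips <- if (flip) stats::runif(2) < 0.5 else c(FALSE, FALSE)
  fl <- function(a) {
    if (flips[1]) a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
    if (flips[2]) a <- a[, rev(seq_len(ncol(a))), drop = FALSE]
    a
  }
  lr <- fl(lr); hr <- fl(hr)
  if (!is.null(pri))
    pri@images <- lapply(pri@images, function(im) {
      im@data <- as.array(fl(im@data)); im
    })
  if (!is.null(cropSize)) {
    cropSize <- as.integer(cropSize)
    if (any(cropSize > dim(lr)))
      stop("crop window larger than the LR image")
    o <- vapply(dim(lr) - cropSize,
                function(m) if (m > 0) sample.int(m + 1L, 1L) - 1L else 0L, 0L)
    lr <- lr[o[1] + seq_len(cropSize), o[2] + seq_len(cropSize), drop = FALSE]
    hsel1 <- fac * o[1] + seq_len(fac * cropSize)
    hsel2 <- fac * o[2] + seq_len(fac * cropSize)
    hr <- hr[hsel1, hsel2, drop = FALSE]
    if (!is.null(pri))
      pri@images <- lapply(pri@images, function(im) {
        im@data <- as.array(im@data[hsel1, hsel2, drop = FALSE]); im
      })
  }
  TrainingPair(MetabolicMap(lr, voxelSize = pair@lr@voxelSize, tier = "LR"),
               MetabolicMap(hr, voxelSize = pair@hr@voxelSize, tier = "HR"),
               prior = pri, tau = pair@tau, truthMode = pair@truthMode)
}

#' Generate a simulated LR/HR training dataset
#'
#' Draws \code{n} independent phantoms, composes metabolic maps with tau
#' cycling round-robin over the 7-value grid, generates the HR ground truth
#' in the requested mode and the LR input by k-space truncation of the VHR
#' map. Records a train/validation split and a manifest. The whole dataset
#' is a pure function of \code{(config, seed)}.
#'
#' @param n number of pairs (>= 1).
#' @param config a [phantomConfig()]; per-phantom seeds are derived from
#'   \code{seed}.
#' @param seed integer master seed.
#' @param truthMode ground-truth mode for all pairs.
#' @param withPrior attach synthetic anatomical priors to each pair
#'   (implied by \code{truthMode = "fnlm_smooth"}).
#' @param validationFraction fraction of pairs (the trailing ones) marked
#'   \code{"validation"} in the manifest.
#' @param outDir if non-NULL, write NIfTI volumes and a tab-separated
#'   manifest there.
#' @return list with elements \code{pairs} (list of
#'   \linkS4class{TrainingPair}) and \code{manifest} (data.frame with
#'   columns id, tau, truth_mode, split, seed and, when written, paths).
#' @export
generateDataset <- function(n, config = phantomConfig(), seed = config$seed,
                            truthMode = c("kspace_sharp", "fnlm_smooth"),
                            withPrior = FALSE, validationFraction = 0.1,
                            outDir = NULL) {
  truthMode <- match.arg(truthMode)
  if (n < 1) stop("'n' must be >= 1")
  needPrior <- withPrior || truthMode == "fnlm_smooth"
  tg <- tauGrid()
  nTrain <- n - floor(validationFraction * n)
  pairs <- vector("list", n)
  seeds <- (as.numeric(seed) + seq_len(n) * 7919) %% 2147483647
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    seg <- makeSegmentation(cfg)
    tau <- tg[(i - 1L) %% length(tg) + 1L]
    vhr <- composeVHR(seg, tau)
    prior <- if (needPrior) makePriorImages(seg) else NULL
    lr <- fftDownsample(vhr, config$factor)
    if (config$noiseStd > 0)
      lr <- .withSeed(cfg$seed + 1L, addNoise(lr, config$noiseStd))
    hr <- makeHRTruth(vhr, truthMode, lr = lr, prior = prior)
    pairs[[i]] <- TrainingPair(lr, hr, prior = prior, tau = tau,
                               truthMode = truthMode)
  }
  manifest <- data.frame(
    id = sprintf("pair%04d", seq_len(n)),
    tau = vapply(pairs, tumorWeight, 0),
    truth_mode = truthMode,
    split = ifelse(seq_len(n) <= nTrain, "train", "validation"),
    seed = as.integer(seeds), stringsAsFactors = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    lrp <- hrp <- character(n)
    for (i in seq_len(n)) {
      lrp[i] <- file.path(outDir, paste0(manifest$id[i], "_lr.nii.gz"))
      hrp[i] <- file.path(outDir, paste0(manifest$id[i], "_hr.nii.gz"))
      writeVolume(pairs[[i]]@lr, lrp[i])
      writeVolume(pairs[[i]]@hr, hrp[i])
      pri <- priorMaps(pairs[[i]])
      if (!is.null(pri))
        for (nm in names(pri@images))
          writeVolume(pri@images[[nm]],
                      file.path(outDir, sprintf("%s_%s.nii.gz",
                                                manifest$id[i], nm)))
    }
    manifest$lr_path <- lrp
    manifest$hr_path <- hrp
    utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(pairs = pairs, manifest = manifest)
}
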