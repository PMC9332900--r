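## Classical (non-deep) upsamplers: bicubic initialization, (weighted)
## total-variation reconstruction against the k-space degradation operator,
## and feature nonlocal-means reinterpolation guided by anatomical priors.

# Keys cubic-convolution kernel, a = -0.5 (the standard "bicubic").
.keys <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# Interpolation weight matrix (nHR x nLR), cell-centered alignment:
# HR center i (0-based) sits at LR coordinate (i + 0.5)/f - 0.5.
# Edge taps are clamped (replicate). Rows sum to 1 (partition of unity).
.cubicWeights <- function(nLR, factor) {
  nHR <- nLR * factor
  Wm <- matrix(0, nHR, nLR)
  for (i in seq_len(nHR)) {
    u <- (i - 0.5) / factor - 0.5
    base <- floor(u)
    for (m in (base - 1):(base + 2)) {
      w <- .keys(u - m)
      col <- min(max(m, 0), nLR - 1) + 1
      Wm[i, col] <- Wm[i, col] + w
    }
  }
  Wm
}

#' Bicubic upsampling (the I-ISR initialization)
#'
#' Separable cubic-convolution (Keys, a = -0.5) interpolation onto a grid
#' \code{factor} times finer per axis, with cell-centered alignment and
#' replicated edges. Out-of-range values are clipped to
#' \code{[0, 1.05 * max(lr)]} since metabolite maps are non-negative.
#'
#' @param lr LR \linkS4class{MetabolicMap} or 2D array.
#' @param factor integer upsampling factor (>= 1).
#' @return upsampled object (tier \code{"ISR"} for maps).
#' @examples
#' isr <- bicubicUpsample(matrix(runif(64), 8, 8), 4)
#' dim(isr)
#' @export
bicubicUpsample <- function(lr, factor = 4L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("'factor' must be >= 1")
  arr <- .asArr(lr)
  if (factor == 1L) return(.likeMap(lr, arr, tier = "ISR"))
  out <- .cubicWeights(nrow(arr), factor) %*% arr %*%
    t(.cubicWeights(ncol(arr), factor))
  hi <- 1.05 * max(arr)
  out <- pmin(pmax(out, 0), hi)
  if (is(lr, "MetabolicMap")) {
    m <- MetabolicMap(out, voxelSize = lr@voxelSize / factor, tier = "ISR")
    return(m)
  }
  out
}

# forward differences with Neumann boundary (last row/col gradient 0)
.gradX <- function(x) rbind(x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE], 0)
.gradY <- function(x) cbind(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE], 0)
# negative adjoint of (.gradX, .gradY): divergence
.divXY <- function(px, py) {
  H <- nrow(px); W <- ncol(px)
  dx <- rbind(px[1, , drop = FALSE],
              px[2:(H - 1), , drop = FALSE] - px[1:(H - 2), , drop = FALSE],
              -px[H - 1, , drop = FALSE])
  dy <- cbind(py[, 1, drop = FALSE],
              py[, 2:(W - 1), drop = FALSE] - py[, 1:(W - 2), drop = FALSE],
              -py[, W - 1, drop = FALSE])
  dx + dy
}

#' Weighted total-variation solver configuration
#'
#' @param lambda TV regularization weight (>= 0); 0 gives the pure
#'   least-squares data fit.
#' @param epsilon smoothing of the TV norm, \code{sqrt(|grad|^2 + eps^2)}.
#' @param maxIter iteration cap of the accelerated solver.
#' @param tol relative-objective convergence tolerance.
#' @param weightSigma scale of the prior-gradient weights
#'   \code{exp(-|grad prior| / sigma)}; \code{NULL} uses the median of the
#'   nonzero prior gradient magnitude.
#' @return classed parameter list.
#' @export
wtvConfig <- function(lambda = 1e-3, epsilon = 1e-3, maxIter = 200L,
                      tol = 1e-6, weightSigma = NULL) {
  if (lambda < 0) stop("'lambda' must be >= 0")
  if (maxIter < 1) stop("'maxIter' must be >= 1")
  structure(list(lambda = lambda, epsilon = epsilon,
                 maxIter = as.integer(maxIter), tol = tol,
                 weightSigma = weightSigma), class = "WtvConfig")
}

#' Weighted total-variation upsampling
#'
#' Reconstructs the HR map as the minimizer of
#' \deqn{\tfrac12 \|A x - y\|^2 + \lambda \sum_i w_i |\nabla x|_i}
#' where \eqn{A} is the k-space truncation operator of the degradation
#' model. With no prior the weights are uniform (plain TV); with a prior
#' the weights are \code{exp(-|grad prior| / sigma_w)}, relaxing smoothing
#' across anatomical edges (wTV). The TV norm is epsilon-smoothed and the
#' problem solved by monotone accelerated gradient descent (Nesterov
#' momentum, backtracking line search, restart on non-descent), so the
#' returned objective trace is non-increasing.
#'
#' @param lr LR map or array.
#' @param prior optional \linkS4class{PriorImages} on the HR grid.
#' @param cfg a [wtvConfig()].
#' @param factor integer upsampling factor.
#' @return for maps, a \linkS4class{MetabolicMap} (tier \code{"SR"}) with
#'   attribute \code{objective} (the per-iteration objective trace); for
#'   arrays, the array with the same attribute.
#' @export
wtvUpsample <- function(lr, prior = NULL, cfg = wtvConfig(), factor = 4L) {
  y <- .asArr(lr)
  factor <- as.integer(factor)
  hrDim <- dim(y) * factor
  w <- matrix(1, hrDim[1], hrDim[2])
  if (!is.null(prior)) {
    stopifnot(is(prior, "PriorImages"))
    g <- matrix(0, hrDim[1], hrDim[2])
    for (im in prior@images) {
      p <- im@data
      if (!identical(dim(p), hrDim)) stop("prior not on the HR target grid")
      g <- pmax(g, sqrt(.gradX(p)^2 + .gradY(p)^2))
    }
    sw <- cfg$weightSigma
    if (is.null(sw)) sw <- stats::median(g[g > 0])
    if (!is.null(sw) && is.finite(sw) && sw > 0) w <- exp(-g / sw)
  }
  eps2 <- cfg$epsilon^2
  A <- function(x) fftResample(x, dim(y))
  At <- function(r) .fftAdjointDownsample(r, hrDim)
  obj <- function(x) {
    r <- A(x) - y
    phi <- sqrt(.gradX(x)^2 + .gradY(x)^2 + eps2)
    0.5 * sum(r^2) + cfg$lambda * sum(w * phi)
  }
  grad <- function(x) {
    g <- At(A(x) - y)
    if (cfg$lambda > 0) {
      gx <- .gradX(x); gy <- .gradY(x)
      phi <- sqrt(gx^2 + gy^2 + eps2)
      g <- g - cfg$lambda * .divXY(w * gx / phi, w * gy / phi)
    }
    g
  }
  x <- bicubicUpsample(y, factor)
  x <- .asArr(x)
  fx <- obj(x)
  trace <- fx
  z <- x; tmom <- 1; step <- 1
  badRun <- 0L
  for (it in seq_len(cfg$maxIter)) {
    gz <- grad(z)
    fz <- obj(z)
    gn2 <- sum(gz^2)
    repeat {   # backtracking on the majorizer at z
      cand <- z - step * gz
      if (obj(cand) <= fz - 0.5 * step * gn2 || step < 1e-12) break
      step <- step / 2
    }
    fc <- obj(cand)
    if (fc <= fx) {                     # monotone acceptance
      tn <- (1 + sqrt(1 + 4 * tmom^2)) / 2
      z <- cand + ((tmom - 1) / tn) * (cand - x)
      x <- cand; fxNew <- fc; tmom <- tn
      badRun <- 0L
    } else {                            # restart momentum, keep best
      z <- x; tmom <- 1; fxNew <- fx
      badRun <- badRun + 1L
      if (badRun >= 10L) {
        warning("wTV solver stalled (no descent in 10 consecutive iterations)")
        break
      }
    }
    trace <- c(trace, fxNew)
    if (abs(fx - fxNew) <= cfg$tol * max(1, abs(fx)) && badRun == 0L && it > 5)
      { fx <- fxNew; break }
    fx <- fxNew
    step <- min(step * 2, 1e6)
  }
  out <- .likeMap(lr, x, tier = "SR")
  if (is(out, "MetabolicMap")) out@voxelSize <- out@voxelSize / factor
  attr(out, "objective") <- trace
  out
}

#' Feature nonlocal-means reinterpolation with prior MRI
#'
#' Refines an initialized SR map by nonlocal weighted averaging in which
#' the patch-similarity weights come from high-resolution anatomical prior
#' images rather than from the (blurry) metabolic map itself: each HR voxel
#' becomes \code{sum_j w_ij sr_j / sum_j w_ij} over its search window with
#' \code{w_ij = exp(-||f_i - f_j||^2 / h^2)}, where the feature vector f
#' stacks patches of all (per-image z-scored) priors. Weights form a convex
#' combination, so before the optional consistency step the output range is
#' contained in the input range.
#'
#' @param srInit initialized SR map (e.g. bicubic or a network output) on
#'   the HR grid.
#' @param prior \linkS4class{PriorImages} on the same grid.
#' @param patchRadius,searchRadius patch and search half-widths (voxels).
#' @param h similarity bandwidth (> 0) on the z-scored feature scale; small
#'   h approaches the identity.
#' @param lrConsistency if TRUE, finish with a k-space data-consistency
#'   projection replacing the retained low-frequency band by that of
#'   \code{lr}, so degrading the output reproduces the LR input exactly.
#' @param lr LR map, required when \code{lrConsistency} is TRUE.
#' @return refined map of the same kind as \code{srInit} (tier \code{"SR"}).
#' @export
fnlmReinterpolate <- function(srInit, prior, patchRadius = 1L,
                              searchRadius = 4L, h = 0.4,
                              lrConsistency = FALSE, lr = NULL) {
  if (h <= 0) stop("'h' must be > 0")
  stopifnot(is(prior, "PriorImages"))
  arr <- .asArr(srInit)
  pdim <- dim(prior@images[[1L]]@data)
  if (!identical(pdim, dim(arr)))
    stop("prior images are not on the SR grid")
  zs <- lapply(prior@images, function(im) {
    p <- im@data
    s <- stats::sd(p)
    if (s > 0) (p - mean(p)) / s else p * 0
  })
  feat <- array(unlist(zs), dim = c(dim(arr), length(zs)))
  out <- .cppNlmFilter(as.matrix(arr), feat, dim(feat),
                       as.integer(patchRadius), as.integer(searchRadius), h)
  if (lrConsistency) {
    if (is.null(lr)) stop("'lrConsistency' requires the LR map")
    out <- .kspaceDataConsistency(out, .asArr(lr))
  }
  .likeMap(srInit, out, tier = "SR")
}

# Replace the retained central k-space band of x by that of lr:
# x' = x + U(lr - A x) with U the zero-fill upsampler, which is a right
# inverse of the truncation A, so fftResample(x', dim(lr)) == lr exactly.
.kspaceDataConsistency <- function(x, lr) {
  x + fftResample(lr - fftResample(x, dim(lr)), dim(x))
}
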