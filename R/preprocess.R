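## Measured-data conditioning chain: spectral-quality filtering, harmonic
## inpainting of missing voxels, nonlocal-means denoising, and metabolite
## ratio maps.

.asArr <- function(x) if (is(x, "MetabolicMap")) x@data else x

.likeMap <- function(x, arr, tier = NULL) {
  if (is(x, "MetabolicMap")) {
    x@data <- as.array(arr)
    if (!is.null(tier)) x@tier <- tier
    x
  } else as.array(arr)
}

#' Filter voxels by spectral quality
#'
#' Marks voxels whose per-voxel quality score is worse than a threshold as
#' missing (\code{NA}); downstream statistics exclude them and
#' [inpaintMissing()] can fill them. "Worse" is \code{score <= threshold}
#' when higher scores are better (the default), or \code{score >=
#' threshold} otherwise — ties at the threshold are always rejected, which
#' makes the rule deterministic.
#'
#' @param map LR \linkS4class{MetabolicMap} or array.
#' @param quality numeric array of per-voxel quality scores, same grid.
#' @param threshold scalar quality cutoff.
#' @param higherIsBetter direction of the quality score.
#' @return list with \code{map} (the input with failing voxels set to
#'   \code{NA}) and \code{mask} (logical array, TRUE = voxel passes).
#' @export
spectralQualityFilter <- function(map, quality, threshold,
                                  higherIsBetter = TRUE) {
  arr <- .asArr(map)
  quality <- .asArr(quality)
  if (!identical(dim(quality), dim(arr)))
    stop("quality map is not aligned to the metabolite map")
  pass <- if (higherIsBetter) quality > threshold else quality < threshold
  if (all(pass)) {
    if (!any(!is.na(arr))) warning("map has no valid voxels")
    return(list(map = map, mask = array(TRUE, dim(arr))))
  }
  arr[!pass] <- NA_real_
  list(map = .likeMap(map, arr), mask = array(pass, dim(arr)))
}

#' Fill missing voxels by harmonic inpainting
#'
#' Missing (\code{NA}) voxels are replaced by the solution of the discrete
#' Laplace equation with the valid voxels as boundary data, computed by
#' iterated neighborhood means (Jacobi sweeps) until the maximum update
#' falls below \code{tol}. Valid voxels are never modified.
#'
#' @param map map or array containing \code{NA}s at missing voxels.
#' @param mask optional logical array (TRUE = valid); defaults to
#'   \code{!is.na(map)}.
#' @param tol convergence tolerance on the maximum per-iteration change.
#' @param maxIter iteration cap.
#' @return inpainted object of the same kind as \code{map}.
#' @export
inpaintMissing <- function(map, mask = NULL, tol = 1e-6, maxIter = 10000L) {
  arr <- .asArr(map)
  if (is.null(mask)) mask <- !is.na(arr)
  if (!any(mask)) stop("all voxels are missing; nothing to inpaint from")
  if (all(mask)) return(map)
  H <- nrow(arr); W <- ncol(arr)
  x <- arr
  x[!mask] <- mean(arr[mask])
  up <- function(m) rbind(m[-1, , drop = FALSE], m[H, , drop = FALSE])
  dn <- function(m) rbind(m[1, , drop = FALSE], m[-H, , drop = FALSE])
  lf <- function(m) cbind(m[, -1, drop = FALSE], m[, W, drop = FALSE])
  rt <- function(m) cbind(m[, 1, drop = FALSE], m[, -W, drop = FALSE])
  for (it in seq_len(maxIter)) {
    nb <- (up(x) + dn(x) + lf(x) + rt(x)) / 4
    delta <- max(abs(nb[!mask] - x[!mask]))
    x[!mask] <- nb[!mask]
    if (delta < tol) break
  }
  .likeMap(map, x)
}

#' Nonlocal-means denoising
#'
#' Each voxel is replaced by a similarity-weighted average over a search
#' window, with weights \code{exp(-||patch_i - patch_j||^2 / h^2)} computed
#' from the map's own patches (mean squared patch difference). Constant
#' images are preserved exactly; as \code{h} tends to 0 the filter
#' approaches the identity.
#'
#' @param map map or 2D array (NA-free; inpaint first).
#' @param patchRadius patch half-width in voxels.
#' @param searchRadius search-window half-width in voxels.
#' @param h similarity bandwidth (> 0), on the intensity scale of the map;
#'   tune to the noise standard deviation.
#' @return denoised object of the same kind as \code{map}.
#' @export
nlmDenoise <- function(map, patchRadius = 1L, searchRadius = 5L, h = 0.1) {
  if (h <= 0) stop("'h' must be > 0")
  arr <- .asArr(map)
  if (anyNA(arr)) stop("map contains missing voxels; run inpaintMissing first")
  feat <- array(arr, dim = c(dim(arr), 1L))
  out <- .cppNlmFilter(as.matrix(arr), feat, dim(feat),
                       as.integer(patchRadius), as.integer(searchRadius), h)
  .likeMap(map, out)
}

#' Metabolite ratio maps (HGG and TCN)
#'
#' Computes the tumor-contrast ratio maps
#' \code{HGG = (2HG + Gln) / Glu} and \code{TCN = tCho / tNAA} per voxel.
#' Voxels whose denominator falls below \code{epsilon} times the
#' denominator maximum are flagged invalid (\code{NA}), not set to an
#' arbitrary number.
#'
#' @param maps named list of \linkS4class{MetabolicMap}s or arrays; names
#'   used (case-insensitive): \code{hg2} or \code{X2HG}/\code{"2HG"},
#'   \code{gln}, \code{glu}, \code{tcho}, \code{tnaa}. Only the maps needed
#'   for the requested ratios are required.
#' @param ratios which ratios to compute, subset of \code{c("HGG", "TCN")}.
#' @param epsilon relative denominator floor.
#' @return named list of ratio maps (same kind as the inputs).
#' @export
computeRatioMaps <- function(maps, ratios = c("HGG", "TCN"),
                             epsilon = 1e-6) {
  ratios <- match.arg(ratios, several.ok = TRUE)
  nm <- tolower(names(maps))
  names(maps) <- nm
  get1 <- function(keys) {
    hit <- which(nm %in% keys)
    if (!length(hit)) stop("missing required metabolite map: ", keys[1])
    maps[[hit[1]]]
  }
  arrs <- lapply(maps, .asArr)
  d0 <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d0), TRUE)))
    stop("all metabolite maps must share one grid")
  div <- function(num, den) {
    floor_ <- epsilon * max(den, na.rm = TRUE)
    r <- num / den
    r[!is.finite(r) | den < floor_] <- NA_real_
    r
  }
  out <- list()
  if ("HGG" %in% ratios) {
    h2g <- .asArr(get1(c("2hg", "hg2", "x2hg")))
    gln <- .asArr(get1("gln")); glu <- .asArr(get1("glu"))
    out$HGG <- .likeMap(get1("glu"), div(h2g + gln, glu))
  }
  if ("TCN" %in% ratios) {
    tcho <- .asArr(get1("tcho")); tnaa <- .asArr(get1("tnaa"))
    out$TCN <- .likeMap(get1("tnaa"), div(tcho, tnaa))
  }
  out
}

#' Full LR conditioning chain
#'
#' Convenience wrapper running spectral-quality filtering, inpainting and
#' NLM denoising in sequence (the conditioning block of the pipeline).
#' With an all-pass quality mask this is exactly [nlmDenoise()] alone.
#'
#' @inheritParams spectralQualityFilter
#' @inheritParams nlmDenoise
#' @param quality optional quality score array; \code{NULL} skips filtering.
#' @param threshold quality cutoff (used when \code{quality} given).
#' @return list with \code{map} (conditioned map) and \code{mask}.
#' @export
preprocessLR <- function(map, quality = NULL, threshold = -Inf,
                         higherIsBetter = TRUE, patchRadius = 1L,
                         searchRadius = 5L, h = 0.1) {
  mask <- array(TRUE, dim(.asArr(map)))
  if (!is.null(quality)) {
    f <- spectralQualityFilter(map, quality, threshold, higherIsBetter)
    map <- f$map; mask <- f$mask
    if (!all(mask)) map <- inpaintMissing(map, mask)
  }
  list(map = nlmDenoise(map, patchRadius, searchRadius, h), mask = mask)
}
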