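#' @useDynLib MetaboSR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.TIERS <- c("VHR", "HR", "LR", "ISR", "SR")

#' MetabolicMap: a metabolite (or metabolite-ratio) image
#'
#' A 2D slice or 3D volume of one metabolite map together with its voxel
#' size and resolution tier. Missing voxels (for example those removed by
#' spectral-quality filtering) are stored as \code{NA}.
#'
#' @slot data numeric array, 2D or 3D.
#' @slot voxelSize numeric, voxel edge length in mm per spatial axis.
#' @slot tier character, one of \code{"VHR"}, \code{"HR"}, \code{"LR"},
#'   \code{"ISR"}, \code{"SR"}.
#'
#' @examples
#' m <- MetabolicMap(matrix(runif(64), 8, 8), voxelSize = c(5.2, 5.2),
#'                   tier = "LR")
#' dim(m)
#' @export
setClass("MetabolicMap",
  representation(data = "array", voxelSize = "numeric", tier = "character"),
  validity = function(object) {
    d <- object@data
    if (!is.numeric(d)) return("'data' must be a numeric array")
    nd <- length(dim(d))
    if (nd < 2L || nd > 3L) return("'data' must be a 2D or 3D array")
    if (length(object@voxelSize) != nd)
      return("'voxelSize' length must match the number of axes")
    if (any(object@voxelSize <= 0)) return("'voxelSize' must be positive")
    if (length(object@tier) != 1L || !object@tier %in% .TIERS)
      return(paste("'tier' must be one of:", paste(.TIERS, collapse = ", ")))
    TRUE
  })

#' Construct a MetabolicMap
#'
#' @param data numeric matrix or array (2D or 3D).
#' @param voxelSize voxel size in mm, recycled to the number of axes.
#' @param tier resolution tier, see \linkS4class{MetabolicMap}.
#' @return a \linkS4class{MetabolicMap}.
#' @export
MetabolicMap <- function(data, voxelSize = 1, tier = "HR") {
  data <- as.array(data)
  if (is.null(dim(data))) stop("'data' must have dimensions")
  storage.mode(data) <- "double"
  nd <- length(dim(data))
  new("MetabolicMap", data = data,
      voxelSize = as.numeric(rep_len(voxelSize, nd)), tier = tier)
}

#' TissueSegmentation: per-voxel tissue fractions
#'
#' Gray matter (GM), white matter (WM), cerebrospinal fluid (CSF) and tumor
#' (TM) fraction maps on the very-high-resolution grid. Fractions lie in
#' [0, 1] and sum to at most 1 per voxel (the remainder is background).
#'
#' @slot gm,wm,csf,tm numeric arrays of identical dimension.
#' @slot voxelSize numeric, voxel size in mm.
#' @export
setClass("TissueSegmentation",
  representation(gm = "array", wm = "array", csf = "array", tm = "array",
                 voxelSize = "numeric"),
  validity = function(object) {
    dm <- dim(object@gm)
    for (nm in c("wm", "csf", "tm"))
      if (!identical(dim(slot(object, nm)), dm))
        return("all fraction maps must share one grid")
    tol <- 1e-9
    for (nm in c("gm", "wm", "csf", "tm")) {
      f <- slot(object, nm)
      if (min(f) < -tol || max(f) > 1 + tol)
        return(sprintf("'%s' fractions must lie in [0, 1]", nm))
    }
    s <- object@gm + object@wm + object@csf + object@tm
    if (max(s) > 1 + tol)
      return("tissue fractions must sum to at most 1 per voxel")
    TRUE
  })

#' PriorImages: co-registered anatomical priors on the HR grid
#'
#' One or more anatomical contrasts (typical roles: FLAIR, MPRAGE) assumed
#' aligned to the super-resolution target grid and intensity-normalized to
#' [0, 1].
#'
#' @slot images named list of \linkS4class{MetabolicMap}s sharing one grid.
#' @export
setClass("PriorImages",
  representation(images = "list"),
  validity = function(object) {
    if (length(object@images) < 1L) return("at least one prior image needed")
    if (!all(vapply(object@images, is, TRUE, "MetabolicMap")))
      return("all priors must be MetabolicMap objects")
    dm <- dim(object@images[[1L]]@data)
    for (im in object@images)
      if (!identical(dim(im@data), dm)) return("priors must share one grid")
    for (im in object@images) {
      r <- range(im@data, na.rm = TRUE)
      if (r[1] < -1e-9 || r[2] > 1 + 1e-9)
        return("prior intensities must be normalized to [0, 1]")
    }
    TRUE
  })

#' Construct a PriorImages object
#'
#' @param ... \linkS4class{MetabolicMap}s or numeric arrays, optionally
#'   named (e.g. \code{flair = ..., mprage = ...}).
#' @param voxelSize voxel size used when arrays are supplied.
#' @return a \linkS4class{PriorImages}.
#' @export
priorImages <- function(..., voxelSize = 1) {
  imgs <- list(...)
  if (length(imgs) == 1L && is.list(imgs[[1L]]) && !is(imgs[[1L]], "MetabolicMap"))
    imgs <- imgs[[1L]]
  imgs <- lapply(imgs, function(im) {
    if (is(im, "MetabolicMap")) im
    else MetabolicMap(im, voxelSize = voxelSize, tier = "HR")
  })
  if (is.null(names(imgs)) || any(names(imgs) == ""))
    names(imgs) <- paste0("prior", seq_along(imgs))
  new("PriorImages", images = imgs)
}

#' TrainingPair: one LR input with its HR ground truth
#'
#' @slot lr \linkS4class{MetabolicMap}, the low-resolution input.
#' @slot hr \linkS4class{MetabolicMap}, the high-resolution truth; its grid
#'   is 4x the LR grid per in-plane axis (general integer factor allowed).
#' @slot prior a \linkS4class{PriorImages} aligned to the HR grid, or empty.
#' @slot tau numeric, tumor compartment weight used in composition.
#' @slot truthMode \code{"kspace_sharp"} (Fourier-truncated source) or
#'   \code{"fnlm_smooth"} (FNLM-upsampled LR).
#' @export
setClass("TrainingPair",
  representation(lr = "MetabolicMap", hr = "MetabolicMap", prior = "list",
                 tau = "numeric", truthMode = "character"),
  validity = function(object) {
    dl <- dim(object@lr@data); dh <- dim(object@hr@data)
    if (length(dl) != length(dh)) return("lr/hr dimensionality mismatch")
    if (any(dh %% dl != 0L)) return("hr grid must be an integer multiple of lr grid")
    if (!object@truthMode %in% c("kspace_sharp", "fnlm_smooth"))
      return("truthMode must be 'kspace_sharp' or 'fnlm_smooth'")
    if (length(object@prior)) {
      pr <- object@prior[[1L]]
      if (!is(pr, "PriorImages")) return("prior slot must hold a PriorImages")
      if (!identical(dim(pr@images[[1L]]@data), dh))
        return("prior images must be aligned to the hr grid")
    }
    TRUE
  })

#' Construct a TrainingPair
#' @param lr,hr \linkS4class{MetabolicMap}s (LR input, HR truth).
#' @param prior optional \linkS4class{PriorImages} on the HR grid.
#' @param tau tumor weight used for this phantom.
#' @param truthMode ground-truth generation mode.
#' @return a \linkS4class{TrainingPair}.
#' @export
TrainingPair <- function(lr, hr, prior = NULL, tau = NA_real_,
                         truthMode = "kspace_sharp") {
  new("TrainingPair", lr = lr, hr = hr,
      prior = if (is.null(prior)) list() else list(prior),
      tau = as.numeric(tau), truthMode = truthMode)
}

#' MetricReport: per-image quality metrics and group comparisons
#'
#' @slot perImage data.frame with columns \code{image}, \code{method},
#'   \code{metric}, \code{value}.
#' @slot summary data.frame of mean metric per method.
#' @slot tests data.frame of Mann-Whitney U statistics and two-sided
#'   p-values for each contender vs the baseline, per metric.
#' @slot improvements data.frame of percent improvement of each contender
#'   over the baseline, per metric (computed on group means).
#' @slot baseline character, the baseline method name.
#' @export
setClass("MetricReport",
  representation(perImage = "data.frame", summary = "data.frame",
                 tests = "data.frame", improvements = "data.frame",
                 baseline = "character"))

## ---- accessors ----

#' @rdname mapData
#' @export
setMethod("mapData", "MetabolicMap", function(x) x@data)

#' @rdname mapData
#' @export
setMethod("mapData", "TissueSegmentation",
          function(x) list(gm = x@gm, wm = x@wm, csf = x@csf, tm = x@tm))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "MetabolicMap", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "TissueSegmentation", function(x) x@voxelSize)

#' @rdname tier
#' @export
setMethod("tier", "MetabolicMap", function(x) x@tier)

#' @rdname lrMap
#' @export
setMethod("lrMap", "TrainingPair", function(x) x@lr)

#' @rdname hrMap
#' @export
setMethod("hrMap", "TrainingPair", function(x) x@hr)

#' @rdname priorMaps
#' @export
setMethod("priorMaps", "TrainingPair",
          function(x) if (length(x@prior)) x@prior[[1L]] else NULL)

#' @rdname tumorWeight
#' @export
setMethod("tumorWeight", "TrainingPair", function(x) x@tau)

#' @rdname truthMode
#' @export
setMethod("truthMode", "TrainingPair", function(x) x@truthMode)

#' @export
setMethod("dim", "MetabolicMap", function(x) dim(x@data))

#' @export
setMethod("dim", "TissueSegmentation", function(x) dim(x@gm))

## ---- show methods ----

setMethod("show", "MetabolicMap", function(object) {
  cat(sprintf("MetabolicMap [%s] %s, voxel %s mm, range [%.4g, %.4g]%s\n",
              object@tier, paste(dim(object@data), collapse = " x "),
              paste(signif(object@voxelSize, 3), collapse = " x "),
              min(object@data, na.rm = TRUE), max(object@data, na.rm = TRUE),
              if (anyNA(object@data))
                sprintf(", %d missing", sum(is.na(object@data))) else ""))
})

setMethod("show", "TissueSegmentation", function(object) {
  vols <- vapply(mapData(object), sum, 0)
  cat(sprintf("TissueSegmentation %s, voxel %s mm\n",
              paste(dim(object@gm), collapse = " x "),
              paste(signif(object@voxelSize, 3), collapse = " x ")))
  cat("  fraction volumes (voxels): ",
      paste(sprintf("%s=%.0f", names(vols), vols), collapse = ", "), "\n")
})

setMethod("show", "PriorImages", function(object) {
  cat(sprintf("PriorImages: %s on grid %s\n",
              paste(names(object@images), collapse = ", "),
              paste(dim(object@images[[1L]]@data), collapse = " x ")))
})

setMethod("show", "TrainingPair", function(object) {
  cat(sprintf("TrainingPair [%s] LR %s -> HR %s, tau=%.2g%s\n",
              object@truthMode, paste(dim(object@lr@data), collapse = "x"),
              paste(dim(object@hr@data), collapse = "x"), object@tau,
              if (length(object@prior)) ", with priors" else ""))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport (baseline:", object@baseline, ")\n\n")
  print(format(object@summary, digits = 4), row.names = FALSE)
  if (nrow(object@improvements)) {
    cat("\nImprovement over baseline (% of group mean):\n")
    print(format(object@improvements, digits = 4), row.names = FALSE)
  }
  if (nrow(object@tests)) {
    cat("\nMann-Whitney U vs baseline (* p < 0.05):\n")
    print(format(object@tests, digits = 4), row.names = FALSE)
  }
})
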