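#' @import methods
NULL

#' Extract the voxel array of an image object
#'
#' @param x a \linkS4class{MetabolicMap} or \linkS4class{TissueSegmentation}.
#' @return For a \code{MetabolicMap}, the numeric array; for a
#'   \code{TissueSegmentation}, a named list of fraction arrays.
#' @export
setGeneric("mapData", function(x) standardGeneric("mapData"))

#' Voxel size in millimetres
#' @param x an image object.
#' @return numeric vector, one entry per spatial axis.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Resolution tier of a metabolic map
#'
#' One of \code{"VHR"}, \code{"HR"}, \code{"LR"}, \code{"ISR"}, \code{"SR"}:
#' very-high-resolution source, high-resolution truth, low-resolution
#' acquisition, interpolation-initialized input, super-resolved output.
#' @param x a \linkS4class{MetabolicMap}.
#' @return character scalar.
#' @export
setGeneric("tier", function(x) standardGeneric("tier"))

#' Low-resolution member of a training pair
#' @param x a \linkS4class{TrainingPair}.
#' @return a \linkS4class{MetabolicMap}.
#' @export
setGeneric("lrMap", function(x) standardGeneric("lrMap"))

#' High-resolution ground-truth member of a training pair
#' @param x a \linkS4class{TrainingPair}.
#' @return a \linkS4class{MetabolicMap}.
#' @export
setGeneric("hrMap", function(x) standardGeneric("hrMap"))

#' Anatomical prior images attached to a training pair
#' @param x a \linkS4class{TrainingPair}.
#' @return a \linkS4class{PriorImages} or \code{NULL}.
#' @export
setGeneric("priorMaps", function(x) standardGeneric("priorMaps"))

#' Tumor intensity weight of a simulated pair
#' @param x a \linkS4class{TrainingPair}.
#' @return numeric scalar (the tumor compartment weight tau).
#' @export
setGeneric("tumorWeight", function(x) standardGeneric("tumorWeight"))

#' Ground-truth generation mode of a training pair
#' @param x a \linkS4class{TrainingPair}.
#' @return \code{"kspace_sharp"} or \code{"fnlm_smooth"}.
#' @export
setGeneric("truthMode", function(x) standardGeneric("truthMode"))
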