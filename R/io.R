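## NIfTI-1 volume I/O for metabolite maps (RNifti-backed).

#' Read a metabolite map from a NIfTI-1 file
#'
#' @param path path to a \code{.nii} / \code{.nii.gz} file.
#' @param tier resolution tier to tag the map with.
#' @return a \linkS4class{MetabolicMap} with voxel sizes taken from the
#'   NIfTI header.
#' @export
readVolume <- function(path, tier = "LR") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  arr <- array(as.numeric(img), dim = dim(img))
  dm <- dim(arr)
  keep <- dm > 1L
  if (sum(keep) >= 2L && any(!keep)) {
    arr <- array(arr, dim = dm[keep])   # drop singleton axes
    dm <- dim(arr)
  }
  if (length(dm) < 2L || length(dm) > 3L)
    stop("volume in '", path, "' is ", length(dm),
         "-dimensional; expected a 2D or 3D map")
  vs <- RNifti::pixdim(img)[seq_along(dm)]
  MetabolicMap(arr, voxelSize = vs, tier = tier)
}

#' Write a metabolite map as NIfTI-1
#'
#' Voxel sizes are stored in the header, so an LR map written alongside its
#' x4 HR counterpart carries 4x the in-plane voxel size.
#'
#' @param map a \linkS4class{MetabolicMap} (or numeric array).
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param voxelSize voxel size used when an array is supplied.
#' @return the path, invisibly.
#' @export
writeVolume <- function(map, path, voxelSize = 1) {
  if (is(map, "MetabolicMap")) {
    arr <- map@data
    vs <- map@voxelSize
  } else {
    arr <- as.array(map)
    vs <- rep_len(voxelSize, length(dim(arr)))
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}
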