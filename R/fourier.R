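## k-space (Fourier-domain) resampling: the forward degradation operator of
## the acquisition model (low resolution = truncation of the image spectrum)
## and its adjoint/zero-fill inverse.

# Signed DFT frequencies retained for a band of m samples. Convention
# (fixed for reproducibility): for even m the half-open, negative-inclusive
# band -m/2 ... m/2-1; for odd m the symmetric band -(m-1)/2 ... (m-1)/2.
.bandFreqs <- function(m) {
  if (m %% 2L == 0L) seq.int(-m %/% 2L, m %/% 2L - 1L)
  else seq.int(-(m - 1L) %/% 2L, (m - 1L) %/% 2L)
}

# Map signed frequencies to 1-based R indices of an unshifted length-n DFT.
.freqIndex <- function(k, n) (k %% n) + 1L

# Per-axis spectral transfer matrix T (M x N) realizing truncation (M < N)
# or zero-fill (M > N). Real signals stay Hermitian: when the band edge
# m/2 exists (m = min(M, N) even), truncation folds the +m/2 source
# coefficient into the aliased -m/2 bin, and zero-filling splits the source
# -m/2 coefficient half onto each of the +/- m/2 destinations. With this
# convention down(up(x)) is the identity and the imaginary residue of a
# real input is at rounding level.
.transferMatrix <- function(N, M) {
  m <- min(M, N)
  B <- .bandFreqs(m)
  Tm <- matrix(0, M, N)
  Tm[cbind(.freqIndex(B, M), .freqIndex(B, N))] <- 1
  if (m %% 2L == 0L && M != N) {
    edge <- m %/% 2L
    if (N > M) {
      Tm[.freqIndex(-edge, M), .freqIndex(edge, N)] <-
        Tm[.freqIndex(-edge, M), .freqIndex(edge, N)] + 1
    } else {
      Tm[.freqIndex(-edge, M), .freqIndex(-edge, N)] <- 0.5
      Tm[.freqIndex(edge, M), .freqIndex(-edge, N)] <- 0.5
    }
  }
  Tm
}

# Apply matrix Tm along one axis of a (complex) array.
.applyAxis <- function(X, Tm, axis) {
  d <- dim(X)
  if (length(d) == 2L) {
    if (axis == 1L) return(Tm %*% X)
    return(X %*% t(Tm))
  }
  perm <- c(axis, setdiff(seq_along(d), axis))
  Xp <- aperm(X, perm)
  dp <- dim(Xp)
  dim(Xp) <- c(dp[1], prod(dp[-1]))
  Yp <- Tm %*% Xp
  dim(Yp) <- c(nrow(Tm), dp[-1])
  aperm(Yp, order(perm))
}

#' Resample an image by spectral truncation or zero-filling
#'
#' Core k-space resampling primitive. Downsampling retains the central
#' (lowest) frequencies of the discrete spectrum; upsampling zero-fills the
#' spectrum. Scaling is DC-preserving: a constant image maps to the same
#' constant on any grid. Per axis the retained band for m samples is the
#' negative-inclusive set \code{-m/2 ... m/2-1} (even m), with a Hermitian
#' band-edge convention: truncation folds the \code{+m/2} source
#' coefficient into its alias \code{-m/2}, zero-filling splits it half
#' onto each of \code{+/-m/2}, so real images stay real to rounding and
#' \code{fftDownsample(fftUpsample(x, f), f) == x}. The output is the real
#' part of the inverse transform.
#'
#' @param x a \linkS4class{MetabolicMap} or numeric array (2D or 3D).
#' @param targetDim integer vector, the output grid (any sizes, e.g. the
#'   full-scale 256x256x176 to 184x184x128 truncation).
#' @param tier tier label for the result when \code{x} is a MetabolicMap;
#'   \code{NULL} keeps the input tier.
#' @return object of the same kind as \code{x} on the target grid.
#' @seealso [fftDownsample()], [fftUpsample()] for the integer-factor
#'   wrappers used by the x4 degradation chain.
#' @export
fftResample <- function(x, targetDim, tier = NULL) {
  if (is(x, "MetabolicMap")) {
    arr <- x@data
    out <- fftResample(arr, targetDim)
    sc <- dim(arr) / dim(out)
    return(MetabolicMap(out, voxelSize = x@voxelSize * sc,
                        tier = if (is.null(tier)) x@tier else tier))
  }
  dm <- dim(x)
  targetDim <- as.integer(round(targetDim))
  if (length(targetDim) != length(dm))
    stop("'targetDim' must give one size per axis")
  if (any(targetDim < 1L)) stop("'targetDim' must be positive")
  Y <- stats::fft(x)
  for (a in seq_along(dm))
    if (targetDim[a] != dm[a])
      Y <- .applyAxis(Y, .transferMatrix(dm[a], targetDim[a]), a)
  Re(stats::fft(Y, inverse = TRUE)) / prod(dm)
}

#' Downsample a map by k-space truncation
#'
#' Realizes the forward degradation operator: the high-resolution spectrum
#' is truncated to its central band and inverse-transformed, producing the
#' blurring and Gibbs ringing characteristic of low-resolution MRSI
#' acquisition. DC-preserving: constants map to themselves.
#'
#' @param x map or array; every axis must be divisible by its factor.
#' @param factor integer downsampling factor, scalar or per axis.
#' @param tier tier label for MetabolicMap results (default \code{"LR"}).
#' @return resampled object with each axis divided by \code{factor}.
#' @examples
#' hr <- matrix(0.37, 32, 32)
#' lr <- fftDownsample(hr, 4)   # constant preserved exactly
#' @export
fftDownsample <- function(x, factor, tier = "LR") {
  dm <- if (is(x, "MetabolicMap")) dim(x@data) else dim(x)
  factor <- rep_len(as.integer(factor), length(dm))
  if (any(factor < 1L)) stop("'factor' must be a positive integer")
  if (any(dm %% factor != 0L))
    stop(sprintf("image dimensions (%s) are not divisible by factor (%s)",
                 paste(dm, collapse = "x"), paste(factor, collapse = "x")))
  fftResample(x, dm %/% factor, tier = tier)
}

#' Upsample a map by zero-filled k-space interpolation
#'
#' Zero-pads the centered spectrum onto a finer grid (sinc interpolation).
#' Utility counterpart of [fftDownsample()]; the learning pipeline
#' initializes with bicubic interpolation instead.
#'
#' @inheritParams fftDownsample
#' @export
fftUpsample <- function(x, factor, tier = "ISR") {
  dm <- if (is(x, "MetabolicMap")) dim(x@data) else dim(x)
  factor <- rep_len(as.integer(factor), length(dm))
  if (any(factor < 1L)) stop("'factor' must be a positive integer")
  fftResample(x, dm * factor, tier = tier)
}

# Adjoint of the truncation operator A = fftResample(., targetDim):
# A* y = Re(IFFT_N(T^t FFT_M(y))) / N with the transposed transfer
# matrices. Used by the variational (wTV) solver.
.fftAdjointDownsample <- function(y, fullDim) {
  dm <- dim(y)
  Y <- stats::fft(y)
  for (a in seq_along(dm))
    if (fullDim[a] != dm[a])
      Y <- .applyAxis(Y, t(.transferMatrix(fullDim[a], dm[a])), a)
  Re(stats::fft(Y, inverse = TRUE)) / prod(fullDim)
}

#' Add i.i.d. Gaussian noise to a map
#'
#' The additive noise term of the degradation model. Uses the current R
#' random stream, so results are reproducible under \code{set.seed}.
#'
#' @param x map or array.
#' @param std noise standard deviation (>= 0).
#' @return object of the same kind as \code{x}.
#' @export
addNoise <- function(x, std) {
  if (length(std) != 1L || is.na(std) || std < 0)
    stop("'std' must be a single non-negative number")
  if (std == 0) return(x)
  if (is(x, "MetabolicMap")) {
    x@data <- x@data + array(stats::rnorm(length(x@data), sd = std),
                             dim = dim(x@data))
    return(x)
  }
  x + array(stats::rnorm(length(x), sd = std), dim = dim(x))
}
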