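#' Estimate the speckle grain size of a frame
#'
#' Returns the full width at half maximum (in pixels) of the normalized
#' autocovariance of the mean-subtracted intensity, averaged over the row
#' and column 1D profiles through the autocovariance peak, with sub-pixel
#' linear interpolation at the half-height crossings. The autocovariance
#' is computed circularly via the FFT, which is accurate while the grain
#' size is small compared to the frame.
#'
#' The estimate is invariant to affine rescaling of the intensities. For
#' pixelwise-independent noise the autocovariance is delta-like and the
#' estimate falls to about one pixel.
#'
#' @param frame A [speckle_frame()] of at least 64 x 64 pixels with
#'   non-zero intensity variance.
#' @return Speckle FWHM in pixels (positive scalar).
#' @export
estimate_speckle_size <- function(frame) {
  stopifnot(inherits(frame, "speckle_frame"))
  x <- frame$intensity
  if (nrow(x) < 64 || ncol(x) < 64)
    stop("frame must be at least 64 x 64 for a stable autocovariance")
  x <- x - mean(x)
  if (all(x == 0)) stop("zero-variance frame: speckle size undefined")
  h <- nrow(x); w <- ncol(x)
  ac <- Re(stats::fft(Mod(stats::fft(x))^2, inverse = TRUE)) / (h * w)
  ac <- ac / ac[1, 1]
  # circular lags: profile through the zero-lag peak
  row_prof <- c(ac[(h %/% 2 + 2):h, 1], ac[seq_len(h %/% 2 + 1), 1])
  col_prof <- c(ac[1, (w %/% 2 + 2):w], ac[1, seq_len(w %/% 2 + 1)])
  mean(c(profile_fwhm(row_prof, h - h %/% 2),
         profile_fwhm(col_prof, w - w %/% 2)))
}

# FWHM of a 1D profile with its peak at index `center`, by linear
# interpolation at the first 0.5 crossing on each side. `vals` passed to
# the helper start at the lag-0 peak, so lag of vals[i] is i - 1.
profile_fwhm <- function(p, center) {
  half_width <- function(vals) {
    below <- which(vals < 0.5)
    if (!length(below)) return(length(vals) - 1)  # never crosses: cap
    i <- below[1]
    (i - 2) + (vals[i - 1] - 0.5) / (vals[i - 1] - vals[i])
  }
  right <- half_width(p[center:length(p)])
  left <- half_width(p[center:1])
  left + right
}

#' Nyquist sampling check for speckle frames
#'
#' Spatial contrast is artificially depressed when speckle grains are
#' smaller than a pixel, because each pixel then averages several
#' independent grains. The check estimates the speckle/pixel ratio from
#' the frame itself and passes when it exceeds one, the sampling condition
#' maintained by the acquisition this package emulates.
#'
#' @param frame A [speckle_frame()] (same preconditions as
#'   [estimate_speckle_size()]).
#' @return A list with `ratio` (the estimated speckle size in pixels) and
#'   `pass` (`ratio > 1`).
#' @export
check_nyquist <- function(frame) {
  ratio <- estimate_speckle_size(frame)
  list(ratio = ratio, pass = ratio > 1)
}
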