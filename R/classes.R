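#' Construct a raw speckle frame
#'
#' A speckle frame is one single-channel intensity image together with the
#' acquisition metadata needed to interpret it: the camera exposure time and
#' the sensor bit depth. Intensities are stored as a numeric matrix in
#' digital numbers (DN); they may be integer-valued (quantized sensor
#' output) or floating point (simulator intermediates, unit-mean patterns).
#'
#' @param intensity Numeric matrix of non-negative intensities (DN).
#' @param exposure_ms Camera exposure time in milliseconds.
#' @param bit_depth Sensor bit depth; one of 8, 12 or 16.
#' @return An object of class `speckle_frame` with fields `intensity`,
#'   `exposure_ms` and `bit_depth`.
#' @seealso [speckle_stack()], [spatial_contrast()]
#' @export
speckle_frame <- function(intensity, exposure_ms = 20, bit_depth = 16) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("`intensity` must be a numeric matrix")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("`intensity` must be finite")
  if (any(intensity < 0))
    stop("`intensity` must be non-negative")
  if (!is.numeric(exposure_ms) || length(exposure_ms) != 1 || exposure_ms <= 0)
    stop("`exposure_ms` must be a positive scalar")
  if (!bit_depth %in% c(8L, 12L, 16L))
    stop("`bit_depth` must be 8, 12 or 16")
  full_scale <- 2^bit_depth - 1
  if (is_integer_valued(intensity) && max(intensity) > full_scale)
    stop("integer-valued intensities exceed full scale 2^bit_depth - 1")
  structure(
    list(intensity = intensity, exposure_ms = as.numeric(exposure_ms),
         bit_depth = as.integer(bit_depth)),
    class = "speckle_frame"
  )
}

is_integer_valued <- function(x) all(abs(x - round(x)) < 1e-9)

#' Construct an ordered stack of speckle frames
#'
#' The unit of pipeline input: frames acquired at a fixed frame rate, all
#' sharing dimensions, exposure time and bit depth.
#'
#' @param frames List of [speckle_frame()] objects (at least one).
#' @param frame_rate_fps Acquisition frame rate in frames per second.
#' @return An object of class `speckle_stack`.
#' @export
speckle_stack <- function(frames, frame_rate_fps = 20) {
  if (!is.list(frames) || length(frames) < 1)
    stop("`frames` must be a non-empty list of speckle_frame objects")
  if (!all(vapply(frames, inherits, logical(1), "speckle_frame")))
    stop("all elements of `frames` must be speckle_frame objects")
  if (!is.numeric(frame_rate_fps) || frame_rate_fps <= 0)
    stop("`frame_rate_fps` must be positive")
  d1 <- dim(frames[[1]]$intensity)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!identical(dim(f$intensity), d1))
      stop(sprintf("frame %d has dimensions %s, expected %s", i,
                   paste(dim(f$intensity), collapse = "x"),
                   paste(d1, collapse = "x")))
    if (f$exposure_ms != frames[[1]]$exposure_ms)
      stop(sprintf("frame %d exposure differs from frame 1", i))
    if (f$bit_depth != frames[[1]]$bit_depth)
      stop(sprintf("frame %d bit depth differs from frame 1", i))
  }
  structure(
    list(frames = frames, frame_rate_fps = as.numeric(frame_rate_fps)),
    class = "speckle_stack"
  )
}

#' @export
print.speckle_frame <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<speckle_frame> %d x %d px, exposure %g ms, %d-bit\n",
              d[1], d[2], x$exposure_ms, x$bit_depth))
  cat(sprintf("  intensity: mean %.4g, range [%.4g, %.4g]\n",
              mean(x$intensity), min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
print.speckle_stack <- function(x, ...) {
  d <- dim(x$frames[[1]]$intensity)
  cat(sprintf("<speckle_stack> %d frame(s) of %d x %d px at %g fps, exposure %g ms, %d-bit\n",
              length(x$frames), d[1], d[2], x$frame_rate_fps,
              x$frames[[1]]$exposure_ms, x$frames[[1]]$bit_depth))
  invisible(x)
}

#' @export
dim.speckle_frame <- function(x) dim(x$intensity)

#' @export
dim.speckle_stack <- function(x) dim(x$frames[[1]]$intensity)

#' @export
length.speckle_stack <- function(x) length(x$frames)
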