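#' Write a speckle stack as a multi-page TIFF with JSON sidecar
#'
#' Frames are stored as 16-bit grayscale TIFF pages; integer-valued
#' intensities are scaled by the stack's full scale `2^bit_depth - 1` and
#' round-trip losslessly at any supported bit depth. Acquisition metadata
#' (exposure, frame rate, bit depth) and optional provenance (seeds, scene
#' parameters) go to `<path>.json`.
#'
#' @param stack A [speckle_stack()].
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @param extra Named list merged into the sidecar (e.g. seeds, scene).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, extra = list()) {
  stopifnot(inherits(stack, "speckle_stack"))
  f1 <- stack$frames[[1]]
  full_scale <- 2^f1$bit_depth - 1
  pages <- lapply(stack$frames, function(f) f$intensity / full_scale)
  mx <- max(vapply(pages, max, numeric(1)))
  scale <- 1
  if (mx > 1) {  # non-integer (e.g. unit-mean float) data: normalize
    scale <- mx
    pages <- lapply(pages, function(p) p / scale)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- c(list(
    exposure_ms = f1$exposure_ms,
    frame_rate_fps = stack$frame_rate_fps,
    bit_depth = f1$bit_depth,
    n_frames = length(stack$frames),
    intensity_scale = scale
  ), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a speckle stack from a multi-page TIFF or a frame directory
#'
#' Accepts a multi-page TIFF written by [write_stack()] (with its JSON
#' sidecar) or a directory of single-page TIFF/PNG frames, loaded in
#' lexicographic order. Missing metadata defaults to 20 ms exposure at
#' 20 fps with a warning.
#'
#' @param path TIFF file or directory of frames.
#' @param exposure_ms,frame_rate_fps,bit_depth Overrides for missing
#'   sidecar metadata.
#' @return A [speckle_stack()].
#' @export
read_stack <- function(path, exposure_ms = NULL, frame_rate_fps = NULL,
                       bit_depth = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop(sprintf("no frame images found in '%s'", path))
    pages <- lapply(files, read_gray_image)
    meta_file <- file.path(path, "stack.json")
  } else {
    if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
    pages <- tiff::readTIFF(path, all = TRUE)
    pages <- lapply(pages, drop_to_gray)
    meta_file <- sidecar_path(path)
  }
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages))
    if (!identical(dim(pages[[i]]), d1))
      stop(sprintf("frame %d has dimensions %s, expected %s", i,
                   paste(dim(pages[[i]]), collapse = "x"),
                   paste(d1, collapse = "x")))
  meta <- if (file.exists(meta_file))
    jsonlite::read_json(meta_file, simplifyVector = TRUE) else list()
  exposure_ms <- exposure_ms %||% meta$exposure_ms
  frame_rate_fps <- frame_rate_fps %||% meta$frame_rate_fps
  bit_depth <- bit_depth %||% meta$bit_depth
  if (is.null(exposure_ms) || is.null(frame_rate_fps)) {
    warning("no acquisition metadata found; assuming 20 ms exposure at 20 fps")
    exposure_ms <- exposure_ms %||% 20
    frame_rate_fps <- frame_rate_fps %||% 20
  }
  bit_depth <- bit_depth %||% 16L
  scale <- meta$intensity_scale %||% 1
  full_scale <- 2^bit_depth - 1
  frames <- lapply(pages, function(p) {
    intens <- p * scale * full_scale
    if (scale == 1) intens <- round(intens)  # integer-valued storage
    speckle_frame(intens, exposure_ms = exposure_ms, bit_depth = bit_depth)
  })
  speckle_stack(frames, frame_rate_fps = frame_rate_fps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_gray_image <- function(f) {
  p <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
       else tiff::readTIFF(f)
  drop_to_gray(p)
}

drop_to_gray <- function(p) {
  if (length(dim(p)) == 3) p <- p[, , 1]
  p
}

#' Write a numeric map as 32-bit float TIFF with scale sidecar
#'
#' Values are stored normalized by their maximum (recorded in the JSON
#' sidecar) because float TIFF storage covers `[0, 1]`; [read_map()]
#' restores the original scale. Round trips are exact to 32-bit float
#' precision.
#'
#' @param map Numeric matrix (e.g. a contrast or LSPU grid).
#' @param path Output TIFF path.
#' @param extra Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, extra = list()) {
  if (!is.matrix(map) || !is.numeric(map)) stop("`map` must be a numeric matrix")
  scale <- max(map, 1e-300)
  tiff::writeTIFF(pmax(map, 0) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(c(list(value_scale = scale), extra),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @return `read_map()`: the numeric matrix.
#' @export
read_map <- function(path) {
  m <- tiff::readTIFF(path)
  meta_file <- sidecar_path(path)
  scale <- if (file.exists(meta_file))
    jsonlite::read_json(meta_file, simplifyVector = TRUE)$value_scale %||% 1
  else 1
  drop_to_gray(m) * scale
}

#' Write an RGB array as PNG
#'
#' @param rgb `h x w x 3` array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write a label map as a paletted PNG
#'
#' Fixed colors: well = green, marginal = orange, poor = red,
#' invalid = black.
#'
#' @param labels A [classify_regions()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  pal <- list(well = c(0.2, 0.7, 0.3), marginal = c(1, 0.65, 0),
              poor = c(0.85, 0.1, 0.1), invalid = c(0, 0, 0))
  lab <- labels$labels
  out <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  for (name in names(pal)) {
    sel <- lab == name
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- pal[[name]][ch]
      out[, , ch] <- plane
    }
  }
  png::writePNG(out, path)
  invisible(path)
}

#' Write and read demarcation contours as JSON
#'
#' Contours are stored as a list of objects with `row` and `col` arrays
#' (0-based pixel coordinates).
#'
#' @param contours List of two-column matrices from [extract_demarcation()].
#' @param path JSON path.
#' @return `path` (write) or the contour list (read).
#' @export
write_contours <- function(contours, path) {
  payload <- lapply(contours, function(m)
    list(row = unname(m[, 1]), col = unname(m[, 2])))
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(payload)) return(list())
  lapply(seq_len(nrow(payload)), function(i) {
    m <- cbind(row = payload$row[[i]], col = payload$col[[i]])
    m
  })
}

#' Write and read an ROI as JSON
#'
#' @param roi An `roi` object.
#' @param path JSON path.
#' @return `path` (write) or the `roi` (read).
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi"))
  payload <- unclass(roi)
  if (roi$shape == "polygon")
    payload$vertices <- apply(roi$vertices, 2, as.numeric)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(p$shape,
    rectangle = roi_rect(p$r0, p$r1, p$c0, p$c1),
    ellipse = roi_ellipse(p$center_r, p$center_c, p$radius_r, p$radius_c),
    polygon = roi_polygon(p$vertices),
    stop(sprintf("unknown ROI shape '%s'", p$shape))
  )
}
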