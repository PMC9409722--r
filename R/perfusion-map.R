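#' Regions of interest
#'
#' ROIs select pixels for reference statistics (e.g. the healthy-tissue
#' reference of [relative_perfusion()]). Coordinates are 0-based pixel
#' positions; rectangles are half-open `[r0, r1) x [c0, c1)`.
#'
#' @param r0,r1,c0,c1 Rectangle bounds.
#' @return An object of class `roi`.
#' @export
roi_rect <- function(r0, r1, c0, c1) {
  if (r1 <= r0 || c1 <= c0) stop("empty ROI rectangle")
  structure(list(shape = "rectangle", r0 = r0, r1 = r1, c0 = c0, c1 = c1),
            class = "roi")
}

#' @rdname roi_rect
#' @param center_r,center_c Ellipse center (0-based pixels).
#' @param radius_r,radius_c Semi-axes in pixels.
#' @export
roi_ellipse <- function(center_r, center_c, radius_r, radius_c) {
  if (radius_r <= 0 || radius_c <= 0) stop("ROI radii must be positive")
  structure(list(shape = "ellipse", center_r = center_r, center_c = center_c,
                 radius_r = radius_r, radius_c = radius_c),
            class = "roi")
}

#' @rdname roi_rect
#' @param vertices Two-column matrix of `(row, col)` polygon vertices
#'   (at least 3).
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2)
    stop("polygon ROI needs a two-column matrix with >= 3 vertices")
  structure(list(shape = "polygon", vertices = vertices), class = "roi")
}

#' Rasterize an ROI into a logical pixel mask
#'
#' @param roi An `roi` object.
#' @param dims `c(height, width)` of the target frame.
#' @return Logical matrix, `TRUE` inside the ROI.
#' @export
roi_mask <- function(roi, dims) {
  stopifnot(inherits(roi, "roi"), length(dims) == 2)
  h <- dims[1]; w <- dims[2]
  rows <- seq_len(h) - 1
  cols <- seq_len(w) - 1
  m <- switch(roi$shape,
    rectangle = outer(rows >= roi$r0 & rows < roi$r1,
                      cols >= roi$c0 & cols < roi$c1, "&"),
    ellipse = outer(((rows - roi$center_r) / roi$radius_r)^2,
                    ((cols - roi$center_c) / roi$radius_c)^2, "+") <= 1,
    polygon = polygon_mask(roi$vertices, h, w)
  )
  if (!any(m)) stop("ROI does not intersect the frame")
  m
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over the
# pixel grid.
polygon_mask <- function(v, h, w) {
  pr <- rep(seq_len(h) - 1, times = w)
  pc <- rep(seq_len(w) - 1, each = h)
  inside <- logical(h * w)
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    ri <- v[i, 1]; ci <- v[i, 2]
    rj <- v[j, 1]; cj <- v[j, 2]
    cross <- ((ri > pr) != (rj > pr)) &
      (pc < (cj - ci) * (pr - ri) / (rj - ri) + ci)
    inside <- xor(inside, cross & (ri != rj))
    j <- i
  }
  matrix(inside, h, w)
}

#' Mask underexposed pixels
#'
#' Flags pixels whose local mean intensity (over the same sliding window
#' used for the contrast computation) falls below a fraction of the sensor
#' full scale. Contrast values in underexposed areas are dominated by
#' sensor noise and carry no perfusion meaning; downstream they are
#' rendered black and labelled invalid.
#'
#' @param frame A [speckle_frame()].
#' @param threshold_frac Fraction of full scale `(0, 1)` below which a
#'   pixel counts as underexposed (default 0.02).
#' @param window_px Window for the local mean (default 7, matching
#'   [spatial_contrast()]).
#' @return Logical validity matrix: `TRUE` where adequately exposed.
#' @export
mask_underexposed <- function(frame, threshold_frac = 0.02, window_px = 7L) {
  stopifnot(inherits(frame, "speckle_frame"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("`threshold_frac` must be in (0, 1)")
  window_px <- as.integer(window_px)
  half <- (window_px - 1L) %/% 2L
  winmean <- box_sum(pad_symmetric(frame$intensity, half), window_px) / window_px^2
  winmean >= threshold_frac * (2^frame$bit_depth - 1)
}

#' Perfusion relative to a healthy-tissue reference
#'
#' Expresses every pixel's LSPU as a percentage of a reference level taken
#' from an ROI placed on healthy tissue — by default the 95th percentile
#' of the ROI's valid LSPU values, a robust stand-in for the "maximum
#' perfusion in healthy tissue" (the literal maximum is noise-prone).
#'
#' @param pmap A [contrast_to_lspu()] or [average_perfusion_maps()] result.
#' @param reference An [roi_rect()]/[roi_ellipse()]/[roi_polygon()] ROI
#'   containing at least 25 valid pixels.
#' @param statistic `"p95"` (default) or `"mean"` reference statistic.
#' @return An object of class `relative_perfusion_map` with fields
#'   `percent` (0-100+ %), `reference_value` (LSPU) and `valid`.
#' @export
relative_perfusion <- function(pmap, reference, statistic = c("p95", "mean")) {
  stopifnot(inherits(pmap, "perfusion_map"))
  statistic <- match.arg(statistic)
  sel <- roi_mask(reference, dim(pmap$lspu)) & pmap$valid
  if (sum(sel) < 25)
    stop(sprintf("reference ROI contains only %d valid pixels (>= 25 required)",
                 sum(sel)))
  vals <- pmap$lspu[sel]
  ref <- if (statistic == "p95") stats::quantile(vals, 0.95, names = FALSE)
         else mean(vals)
  if (ref <= 0) stop("non-positive reference perfusion value")
  structure(
    list(percent = 100 * pmap$lspu / ref, reference_value = ref,
         valid = pmap$valid),
    class = "relative_perfusion_map"
  )
}

#' Classify tissue by relative perfusion
#'
#' Thresholds the relative-perfusion map into well, marginally and poorly
#' perfused tissue: well at or above `t_well` percent of the reference,
#' poor below `t_marginal`, marginal in between; invalid wherever the
#' input is invalid. The default thresholds (18% / 55%) separate the
#' simulator's default perfusion tiers under the LSPU = 1/K^2 convention;
#' they are a software convention, not clinically validated cut-offs,
#' and should be calibrated against outcome data before clinical
#' interpretation.
#'
#' @param relmap A [relative_perfusion()] result.
#' @param t_marginal,t_well Percent thresholds, `0 < t_marginal < t_well`.
#' @return An object of class `label_map` with a character matrix `labels`
#'   over `well`/`marginal`/`poor`/`invalid` and the thresholds used.
#' @export
classify_regions <- function(relmap, t_marginal = 18, t_well = 55) {
  stopifnot(inherits(relmap, "relative_perfusion_map"))
  if (!(t_marginal > 0 && t_marginal < t_well))
    stop("thresholds must satisfy 0 < t_marginal < t_well")
  p <- relmap$percent
  labels <- matrix("poor", nrow(p), ncol(p))
  labels[p >= t_marginal] <- "marginal"
  labels[p >= t_well] <- "well"
  labels[!relmap$valid] <- "invalid"
  structure(
    list(labels = labels, t_marginal = t_marginal, t_well = t_well),
    class = "label_map"
  )
}

#' Extract demarcation lines between perfusion classes
#'
#' Traces the boundaries between differing non-invalid labels as
#' polylines on the pixel grid (marching-squares style on label
#' transitions): every edge between two 4-adjacent pixels with different
#' valid labels contributes a unit segment on the half-pixel grid, and
#' connected segments are chained into contours. Contours never pass
#' through invalid-labelled regions. A uniform label map yields an empty
#' list.
#'
#' @param labels A [classify_regions()] result.
#' @return List of contours, each a two-column matrix of `(row, col)`
#'   positions in 0-based pixel coordinates (half-integer values: the
#'   lines run between pixel centers).
#' @export
extract_demarcation <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  h <- nrow(lab); w <- ncol(lab)
  # vertical boundary edges: between (r, c) and (r, c+1)
  segs <- list()
  if (w > 1) {
    a <- lab[, -w, drop = FALSE]; b <- lab[, -1, drop = FALSE]
    hit <- which(a != b & a != "invalid" & b != "invalid", arr.ind = TRUE)
    if (nrow(hit)) {
      r <- hit[, 1] - 1; cc <- hit[, 2] - 1  # 0-based pixel coords
      segs <- c(segs, list(cbind(r - 0.5, cc + 0.5, r + 0.5, cc + 0.5)))
    }
  }
  if (h > 1) {
    a <- lab[-h, , drop = FALSE]; b <- lab[-1, , drop = FALSE]
    hit <- which(a != b & a != "invalid" & b != "invalid", arr.ind = TRUE)
    if (nrow(hit)) {
      r <- hit[, 1] - 1; cc <- hit[, 2] - 1
      segs <- c(segs, list(cbind(r + 0.5, cc - 0.5, r + 0.5, cc + 0.5)))
    }
  }
  if (!length(segs)) return(list())
  chain_segments(do.call(rbind, segs))
}

# Chain unit segments (r1, c1, r2, c2) into polylines. Endpoints are on
# the half-integer grid; they are keyed on a doubled integer lattice.
chain_segments <- function(segs) {
  n <- nrow(segs)
  key <- function(r, c) paste(round(2 * r), round(2 * c))
  ends <- new.env(parent = emptyenv())  # endpoint key -> segment ids
  k1 <- key(segs[, 1], segs[, 2])
  k2 <- key(segs[, 3], segs[, 4])
  for (i in seq_len(n)) {
    ends[[k1[i]]] <- c(ends[[k1[i]]], i)
    ends[[k2[i]]] <- c(ends[[k2[i]]], i)
  }
  used <- logical(n)
  walk <- function(start_seg, start_key) {
    path_keys <- character(0)
    cur_key <- start_key
    cur_seg <- start_seg
    repeat {
      used[cur_seg] <<- TRUE
      nxt_key <- if (k1[cur_seg] == cur_key) k2[cur_seg] else k1[cur_seg]
      path_keys <- c(path_keys, cur_key)
      cand <- ends[[nxt_key]]
      cand <- cand[!used[cand]]
      if (!length(cand)) {
        path_keys <- c(path_keys, nxt_key)
        break
      }
      cur_key <- nxt_key
      cur_seg <- cand[1]
    }
    path_keys
  }
  contours <- list()
  # open paths first (endpoints of odd degree), then remaining loops
  for (pass in 1:2) {
    for (i in seq_len(n)) {
      if (used[i]) next
      deg1 <- length(ends[[k1[i]]])
      start <- if (pass == 1) {
        if (deg1 %% 2 == 1) k1[i]
        else if (length(ends[[k2[i]]]) %% 2 == 1) k2[i]
        else next
      } else k1[i]
      pk <- walk(i, start)
      coords <- do.call(rbind, lapply(strsplit(pk, " "), as.numeric)) / 2
      colnames(coords) <- c("row", "col")
      contours[[length(contours) + 1]] <- coords
    }
  }
  contours
}

#' Render a perfusion map in Viridis false color
#'
#' Maps valid pixels through the Viridis colormap after clipping to a
#' display range; invalid (underexposed or border) pixels are rendered
#' exact black, as in clinical perfusion displays. The default range is
#' the 1st-99th percentile of the valid values, which maximizes visual
#' contrast per frame; pass `scaling = "fixed"` with `lo`/`hi` for
#' cross-frame comparability.
#'
#' @param map A `perfusion_map`, `relative_perfusion_map`, or plain
#'   numeric matrix (then `valid` may be supplied).
#' @param scaling `"percentile"` (default) or `"fixed"`.
#' @param lo,hi Display range for fixed scaling.
#' @param probs Length-2 percentile probabilities for percentile scaling.
#' @param valid Optional logical matrix when `map` is a plain matrix.
#' @return An `height x width x 3` RGB array in `[0, 1]`.
#' @export
render_false_color <- function(map, scaling = c("percentile", "fixed"),
                               lo = NULL, hi = NULL, probs = c(0.01, 0.99),
                               valid = NULL) {
  scaling <- match.arg(scaling)
  if (inherits(map, "perfusion_map")) {
    vals <- map$lspu; valid <- map$valid
  } else if (inherits(map, "relative_perfusion_map")) {
    vals <- map$percent; valid <- map$valid
  } else if (is.matrix(map) && is.numeric(map)) {
    vals <- map
    if (is.null(valid)) valid <- matrix(TRUE, nrow(map), ncol(map))
  } else stop("`map` must be a perfusion map, relative map, or matrix")
  if (!any(valid)) stop("no valid pixels to render")
  v <- vals[valid]
  if (scaling == "percentile") {
    rng <- stats::quantile(v, probs, names = FALSE)
  } else {
    if (is.null(lo) || is.null(hi)) stop("fixed scaling requires `lo` and `hi`")
    rng <- c(lo, hi)
  }
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1e-12
  pal <- grDevices::col2rgb(viridisLite::viridis(256L)) / 255
  idx <- pmin(pmax(round((vals - rng[1]) / (rng[2] - rng[1]) * 255) + 1, 1), 256)
  out <- array(0, dim = c(nrow(vals), ncol(vals), 3))
  for (ch in 1:3) {
    plane <- pal[ch, idx]
    dim(plane) <- dim(vals)
    plane[!valid] <- 0
    out[, , ch] <- plane
  }
  out
}

#' Compose white-light and perfusion views side by side
#'
#' Horizontal concatenation in the operating-room display convention:
#' white light on the left, false-color perfusion on the right, separated
#' by a 2-pixel white divider. If the heights differ, the perfusion image
#' is resampled (nearest neighbor, aspect preserved) to match the
#' white-light height.
#'
#' @param white_light RGB array (h x w x 3) or grayscale matrix.
#' @param perfusion_rgb RGB array or grayscale matrix.
#' @return RGB array of height `nrow(white_light)` and width
#'   `w_white + w_perfusion + 2`.
#' @export
compose_side_by_side <- function(white_light, perfusion_rgb) {
  wl <- as_rgb_array(white_light)
  pf <- as_rgb_array(perfusion_rgb)
  if (dim(wl)[1] == 0 || dim(pf)[1] == 0) stop("empty image")
  if (dim(pf)[1] != dim(wl)[1]) {
    scale <- dim(wl)[1] / dim(pf)[1]
    pf <- resample_rgb(pf, dim(wl)[1], max(1L, as.integer(round(dim(pf)[2] * scale))))
  }
  h <- dim(wl)[1]
  divider <- array(1, dim = c(h, 2, 3))
  out <- array(0, dim = c(h, dim(wl)[2] + 2 + dim(pf)[2], 3))
  out[, seq_len(dim(wl)[2]), ] <- wl
  out[, dim(wl)[2] + 1:2, ] <- divider
  out[, (dim(wl)[2] + 3):dim(out)[2], ] <- pf
  out
}

as_rgb_array <- function(x) {
  if (is.matrix(x)) {
    a <- array(0, dim = c(nrow(x), ncol(x), 3))
    for (ch in 1:3) a[, , ch] <- x
    a
  } else if (is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3) {
    x
  } else stop("images must be h x w x 3 arrays or grayscale matrices")
}

resample_rgb <- function(x, h2, w2) {
  ri <- pmin(pmax(round((seq_len(h2) - 0.5) * dim(x)[1] / h2 + 0.5), 1), dim(x)[1])
  ci <- pmin(pmax(round((seq_len(w2) - 0.5) * dim(x)[2] / w2 + 0.5), 1), dim(x)[2])
  x[ri, ci, , drop = FALSE]
}

#' Flat gray white-light placeholder
#'
#' Stands in for a co-registered white-light view in pipelines run on
#' simulated data (no white-light scene synthesis is attempted).
#'
#' @param height_px,width_px Dimensions.
#' @param level Gray level in `[0, 1]`.
#' @return RGB array.
#' @export
white_light_placeholder <- function(height_px, width_px, level = 0.5) {
  array(level, dim = c(height_px, width_px, 3))
}

#' @export
print.relative_perfusion_map <- function(x, ...) {
  v <- x$percent[x$valid]
  cat(sprintf("<relative_perfusion_map> %d x %d px, reference %.4g LSPU\n",
              nrow(x$percent), ncol(x$percent), x$reference_value))
  if (length(v))
    cat(sprintf("  percent (valid): median %.1f%%, range [%.1f%%, %.1f%%]\n",
                stats::median(v), min(v), max(v)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("well", "marginal", "poor", "invalid")))
  cat(sprintf("<label_map> %d x %d px (thresholds %g%% / %g%%)\n",
              nrow(x$labels), ncol(x$labels), x$t_marginal, x$t_well))
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
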