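#' Define a perfusion scene for the speckle simulator
#'
#' A scene is the ground truth the simulator renders: frame dimensions, a
#' background decorrelation time, a set of labelled regions (rectangles or
#' ellipses) carrying their own decorrelation times, the speckle grain size
#' on the sensor, the coherence factor beta, and a radial illumination
#' falloff that models the underexposed periphery of a laparoscopic view.
#'
#' Decorrelation time tau_c is the time over which the speckle field at a
#' pixel decorrelates; it is inversely related to red-blood-cell speed, so
#' well perfused tissue has a short tau_c and ischemic tissue a long one.
#' The default presets (1 / 5 / 50 ms) straddle the 20 ms exposure so that
#' the three tiers produce visibly distinct perfusion-unit levels.
#'
#' Coordinates are 0-based, row-major `(row, col)`; rectangles are half-open
#' `[r0, r1) x [c0, c1)`.
#'
#' @param height_px,width_px Frame dimensions in pixels.
#' @param regions List of regions from [scene_region_rect()] or
#'   [scene_region_ellipse()]; later regions overwrite earlier ones where
#'   they overlap.
#' @param background_tau_c_ms Decorrelation time (ms) outside all regions.
#' @param background_label Label of the background tissue
#'   (default `"well"`).
#' @param speckle_size_px Speckle grain size: full width at half maximum of
#'   the intensity autocovariance, in pixels. Values >= 1 satisfy the
#'   Nyquist sampling requirement; the default 2 oversamples it.
#' @param beta Coherence/sampling factor in (0, 1]: the ground-truth
#'   asymptote of the squared contrast for a static scene.
#' @param illumination_falloff Fractional intensity drop at the frame
#'   corners, in `[0, 1]`; 0 means flat illumination.
#' @param seed Integer seed driving the simulated speckle fields.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(height_px, width_px, regions = list(),
                         background_tau_c_ms = 1,
                         background_label = "well",
                         speckle_size_px = 2, beta = 0.8,
                         illumination_falloff = 0.3, seed = 1L) {
  if (height_px < 1 || width_px < 1) stop("frame dimensions must be positive")
  if (background_tau_c_ms <= 0) stop("`background_tau_c_ms` must be positive")
  if (speckle_size_px < 0.5) stop("`speckle_size_px` must be >= 0.5")
  if (beta <= 0 || beta > 1) stop("`beta` must be in (0, 1]")
  if (illumination_falloff < 0 || illumination_falloff > 1)
    stop("`illumination_falloff` must be in [0, 1]")
  background_label <- match.arg(background_label, c("well", "marginal", "poor"))
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (!inherits(r, "scene_region"))
      stop(sprintf("region %d is not a scene_region", i))
    if (r$tau_c_ms <= 0)
      stop(sprintf("region %d has non-positive tau_c", i))
    if (!region_inside(r, height_px, width_px))
      stop(sprintf("region %d extends outside the %d x %d frame", i,
                   height_px, width_px))
  }
  structure(
    list(height_px = as.integer(height_px), width_px = as.integer(width_px),
         regions = regions, background_tau_c_ms = background_tau_c_ms,
         background_label = background_label,
         speckle_size_px = speckle_size_px, beta = beta,
         illumination_falloff = illumination_falloff, seed = as.integer(seed)),
    class = "scene_params"
  )
}

#' Rectangular scene region
#'
#' @param label One of `"well"`, `"marginal"`, `"poor"`.
#' @param r0,r1,c0,c1 Half-open pixel bounds `[r0, r1) x [c0, c1)`, 0-based.
#' @param tau_c_ms Decorrelation time of the region, in ms.
#' @return A `scene_region` object.
#' @export
scene_region_rect <- function(label, r0, r1, c0, c1, tau_c_ms) {
  label <- match.arg(label, c("well", "marginal", "poor"))
  if (r1 <= r0 || c1 <= c0) stop("empty rectangle")
  structure(list(shape = "rect", label = label,
                 r0 = r0, r1 = r1, c0 = c0, c1 = c1, tau_c_ms = tau_c_ms),
            class = "scene_region")
}

#' Elliptical scene region
#'
#' @inheritParams scene_region_rect
#' @param center_r,center_c Ellipse center in 0-based pixel coordinates.
#' @param radius_r,radius_c Semi-axes in pixels (row and column directions).
#' @return A `scene_region` object.
#' @export
scene_region_ellipse <- function(label, center_r, center_c,
                                 radius_r, radius_c, tau_c_ms) {
  label <- match.arg(label, c("well", "marginal", "poor"))
  if (radius_r <= 0 || radius_c <= 0) stop("ellipse radii must be positive")
  structure(list(shape = "ellipse", label = label,
                 center_r = center_r, center_c = center_c,
                 radius_r = radius_r, radius_c = radius_c,
                 tau_c_ms = tau_c_ms),
            class = "scene_region")
}

region_inside <- function(r, h, w) {
  if (r$shape == "rect") {
    r$r0 >= 0 && r$c0 >= 0 && r$r1 <= h && r$c1 <= w
  } else {
    r$center_r - r$radius_r >= -0.5 && r$center_r + r$radius_r <= h - 0.5 &&
      r$center_c - r$radius_c >= -0.5 && r$center_c + r$radius_c <= w - 0.5
  }
}

region_mask <- function(r, h, w) {
  if (r$shape == "rect") {
    rows <- seq_len(h) - 1L
    cols <- seq_len(w) - 1L
    outer(rows >= r$r0 & rows < r$r1, cols >= r$c0 & cols < r$c1, "&")
  } else {
    rows <- (seq_len(h) - 1L - r$center_r) / r$radius_r
    cols <- (seq_len(w) - 1L - r$center_c) / r$radius_c
    outer(rows^2, cols^2, "+") <= 1
  }
}

#' Render a scene into a ground-truth perfusion phantom
#'
#' Produces the per-pixel grids downstream stages are tested against: the
#' decorrelation-time map, the tissue label map, and the illumination field
#' (radially decreasing from the frame center, reaching
#' `1 - illumination_falloff` at the corners).
#'
#' @param params A [scene_params()] object.
#' @return An object of class `perfusion_phantom` with fields `tau_c_map`
#'   (ms), `label_map` (character matrix over well/marginal/poor),
#'   `illumination_map` (in (0, 1]) and `params`.
#' @export
make_phantom <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$height_px
  w <- params$width_px
  tau <- matrix(params$background_tau_c_ms, h, w)
  lab <- matrix(params$background_label, h, w)
  for (r in params$regions) {
    m <- region_mask(r, h, w)
    tau[m] <- r$tau_c_ms
    lab[m] <- r$label
  }
  # radial falloff: 1 at center, 1 - falloff at the corners
  rows <- (seq_len(h) - 1 - (h - 1) / 2)
  cols <- (seq_len(w) - 1 - (w - 1) / 2)
  rmax <- sqrt(((h - 1) / 2)^2 + ((w - 1) / 2)^2)
  radial <- sqrt(outer(rows^2, cols^2, "+")) / max(rmax, 1)
  illum <- 1 - params$illumination_falloff * radial^2
  structure(
    list(tau_c_map = tau, label_map = lab, illumination_map = illum,
         params = params),
    class = "perfusion_phantom"
  )
}

#' Default three-tier perfusion scene
#'
#' Three vertical bands of equal width: well perfused background on the
#' left (tau_c 1 ms), a marginally perfused middle band (5 ms) and a poorly
#' perfused right band (50 ms). This is the stock phantom used throughout
#' the test-suite examples; the tiers mimic an intestinal segment with
#' progressively devascularized mesentery.
#'
#' @param height_px,width_px Frame dimensions (default 192 x 192).
#' @param tau_well,tau_marginal,tau_poor Decorrelation times (ms) of the
#'   three tiers.
#' @param ... Passed on to [scene_params()].
#' @return A `scene_params` object.
#' @export
default_scene <- function(height_px = 192, width_px = 192,
                          tau_well = 1, tau_marginal = 5, tau_poor = 50,
                          ...) {
  b1 <- floor(width_px / 3)
  b2 <- floor(2 * width_px / 3)
  scene_params(
    height_px, width_px,
    regions = list(
      scene_region_rect("marginal", 0, height_px, b1, b2, tau_marginal),
      scene_region_rect("poor", 0, height_px, b2, width_px, tau_poor)
    ),
    background_tau_c_ms = tau_well,
    ...
  )
}

#' @export
print.perfusion_phantom <- function(x, ...) {
  cat(sprintf("<perfusion_phantom> %d x %d px\n",
              nrow(x$tau_c_map), ncol(x$tau_c_map)))
  tab <- table(x$label_map)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  tau_c: %g..%g ms; illumination: %.3f..%.3f\n",
              min(x$tau_c_map), max(x$tau_c_map),
              min(x$illumination_map), max(x$illumination_map)))
  invisible(x)
}
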