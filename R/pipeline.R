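#' Pipeline configuration
#'
#' Bundles every tunable of the processing chain; defaults match the
#' emulated clinical configuration (7 x 7 contrast window; the simulator
#' supplies 20 ms exposure at 20 fps) and this package's documented
#' conventions (LSPU = 1/K^2, 95th-percentile reference, 18% / 55%
#' classification thresholds).
#'
#' @param window_px Odd contrast window side (default 7).
#' @param lspu_form `"k2"` (1/K^2, default) or `"k1"` (1/K).
#' @param lspu_cap LSPU saturation value.
#' @param underexposure_threshold_frac Fraction of full scale below which
#'   a pixel is masked as underexposed.
#' @param t_marginal,t_well Classification thresholds in percent of the
#'   reference perfusion, `0 < t_marginal < t_well`.
#' @param reference_roi ROI for the healthy-tissue reference, or `NULL`
#'   to use the whole frame (the p95 statistic then reads the reference
#'   off the best-perfused tissue in view).
#' @param reference_statistic `"p95"` or `"mean"`.
#' @param color_scaling `"percentile"` or `"fixed"`.
#' @param color_lo,color_hi Display range for fixed color scaling.
#' @param n_average Number of leading frames to average (NULL = all).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_px = 7L, lspu_form = "k2", lspu_cap = 1e4,
                            underexposure_threshold_frac = 0.02,
                            t_marginal = 18, t_well = 55,
                            reference_roi = NULL, reference_statistic = "p95",
                            color_scaling = "percentile",
                            color_lo = NULL, color_hi = NULL,
                            n_average = NULL) {
  window_px <- as.integer(window_px)
  if (window_px < 3L || window_px %% 2L == 0L)
    stop("`window_px` must be an odd integer >= 3")
  lspu_form <- match.arg(lspu_form, c("k2", "k1"))
  if (lspu_cap <= 0) stop("`lspu_cap` must be positive")
  if (underexposure_threshold_frac <= 0 || underexposure_threshold_frac >= 1)
    stop("`underexposure_threshold_frac` must be in (0, 1)")
  if (!(t_marginal > 0 && t_marginal < t_well))
    stop("thresholds must satisfy 0 < t_marginal < t_well")
  if (!is.null(reference_roi) && !inherits(reference_roi, "roi"))
    stop("`reference_roi` must be an roi object or NULL")
  reference_statistic <- match.arg(reference_statistic, c("p95", "mean"))
  color_scaling <- match.arg(color_scaling, c("percentile", "fixed"))
  if (color_scaling == "fixed" && (is.null(color_lo) || is.null(color_hi)))
    stop("fixed color scaling requires `color_lo` and `color_hi`")
  if (!is.null(n_average) && n_average < 1)
    stop("`n_average` must be >= 1 or NULL")
  structure(
    list(window_px = window_px, lspu_form = lspu_form, lspu_cap = lspu_cap,
         underexposure_threshold_frac = underexposure_threshold_frac,
         t_marginal = t_marginal, t_well = t_well,
         reference_roi = reference_roi,
         reference_statistic = reference_statistic,
         color_scaling = color_scaling,
         color_lo = color_lo, color_hi = color_hi,
         n_average = if (is.null(n_average)) NULL else as.integer(n_average)),
    class = "pipeline_config"
  )
}

#' Run the full perfusion-imaging pipeline
#'
#' Chains the whole processing path on a speckle stack: read (if given a
#' path) -> per-frame spatial contrast -> LSPU -> temporal average ->
#' underexposure mask -> relative perfusion -> classification ->
#' demarcation -> false-color render -> side-by-side composition. All
#' artifacts plus a JSON summary (per-label pixel fractions, reference
#' value, the complete effective configuration, package version) are
#' written under `out_dir`. The run is deterministic: identical config and
#' input produce byte-identical summaries.
#'
#' @param config A [pipeline_config()].
#' @param input A [speckle_stack()] or a path accepted by [read_stack()].
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output and just returns the results.
#' @param white_light Optional RGB array; defaults to a flat gray
#'   placeholder.
#' @param verbose Log each stage (dimensions, parameters) to the console.
#' @return Invisibly, a list with the intermediate objects (`stack`,
#'   `perfusion`, `relative`, `labels`, `contours`, `render`, `composite`)
#'   and the `summary` list.
#' @export
run_pipeline <- function(config, input, out_dir = NULL, white_light = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(...) if (verbose) message(sprintf(...))

  stack <- if (inherits(input, "speckle_stack")) input else read_stack(input)
  d <- dim(stack)
  log_stage("read: %d frame(s) of %d x %d px", length(stack), d[1], d[2])

  n_use <- min(config$n_average %||% length(stack), length(stack))
  maps <- vector("list", n_use)
  for (i in seq_len(n_use)) {
    cm <- spatial_contrast(stack$frames[[i]], window_px = config$window_px)
    maps[[i]] <- contrast_to_lspu(cm, lspu_cap = config$lspu_cap,
                                  form = config$lspu_form)
  }
  pmap <- average_perfusion_maps(maps)
  log_stage("contrast/LSPU: window %d, form %s, averaged %d frame(s)",
            config$window_px, config$lspu_form, n_use)

  # exposure mask from the temporal-mean intensity
  mean_int <- Reduce(`+`, lapply(stack$frames[seq_len(n_use)],
                                 function(f) f$intensity)) / n_use
  mean_frame <- speckle_frame(mean_int,
                              exposure_ms = stack$frames[[1]]$exposure_ms,
                              bit_depth = stack$frames[[1]]$bit_depth)
  exposed <- mask_underexposed(mean_frame,
                               threshold_frac = config$underexposure_threshold_frac,
                               window_px = config$window_px)
  pmap$valid <- pmap$valid & exposed
  log_stage("mask: %.1f%% of pixels adequately exposed", 100 * mean(exposed))

  ref_roi <- config$reference_roi %||% roi_rect(0, d[1], 0, d[2])
  relmap <- relative_perfusion(pmap, ref_roi,
                               statistic = config$reference_statistic)
  labels <- classify_regions(relmap, t_marginal = config$t_marginal,
                             t_well = config$t_well)
  contours <- extract_demarcation(labels)
  log_stage("classify: reference %.4g LSPU, %d demarcation contour(s)",
            relmap$reference_value, length(contours))

  render <- if (config$color_scaling == "fixed")
    render_false_color(relmap, scaling = "fixed",
                       lo = config$color_lo, hi = config$color_hi)
  else render_false_color(relmap)
  wl <- white_light %||% white_light_placeholder(d[1], d[2])
  composite <- compose_side_by_side(wl, render)

  lab_f <- factor(labels$labels, levels = c("well", "marginal", "poor", "invalid"))
  fractions <- as.list(table(lab_f) / length(lab_f))
  cfg_echo <- config
  cfg_echo$reference_roi <- if (is.null(config$reference_roi)) "whole-frame"
                            else unclass(config$reference_roi)
  summary <- list(
    package_version = as.character(utils::packageVersion("speckleflow")),
    n_frames_in = length(stack),
    n_frames_averaged = n_use,
    frame_height = d[1], frame_width = d[2],
    exposure_ms = stack$frames[[1]]$exposure_ms,
    frame_rate_fps = stack$frame_rate_fps,
    reference_value_lspu = relmap$reference_value,
    label_fractions = fractions,
    n_contours = length(contours),
    config = unclass(cfg_echo)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_map(pmap$lspu, file.path(out_dir, "perfusion.tiff"))
    write_map(relmap$percent, file.path(out_dir, "relative_percent.tiff"))
    write_label_png(labels, file.path(out_dir, "labels.png"))
    write_contours(contours, file.path(out_dir, "contours.json"))
    write_rgb_png(render, file.path(out_dir, "perfusion.png"))
    write_rgb_png(composite, file.path(out_dir, "side_by_side.png"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage("wrote artifacts to %s", out_dir)
  }

  invisible(list(stack = stack, perfusion = pmap, relative = relmap,
                 labels = labels, contours = contours, render = render,
                 composite = composite, summary = summary))
}
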