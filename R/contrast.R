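#' Per-pixel spatial speckle contrast
#'
#' Computes the spatial speckle contrast K = sigma / mean over a sliding
#' square window centered on every pixel: the population standard
#' deviation of the window divided by its mean intensity. Lower contrast
#' means more motion blur within the exposure, i.e. more flow. The default
#' 7 x 7 window matches the clinical processing configuration the package
#' emulates.
#'
#' The map is computed with running box sums (integral-image style), which
#' agrees with an explicit per-window loop to floating-point tolerance.
#' With `edge = "reflect"` the frame is symmetrically padded so the output
#' has the input's dimensions, and `border_mask` flags the
#' `(window_px - 1)/2`-pixel rim whose windows overlapped the edge. With
#' `edge = "valid"` only fully interior windows are returned (the output
#' shrinks by `window_px - 1` in each dimension). Windows with zero mean
#' (fully dark) yield K = 0 and are flagged in `border_mask`; such pixels
#' are underexposed and are masked downstream.
#'
#' @param frame A [speckle_frame()] at least `window_px` pixels in each
#'   dimension.
#' @param window_px Odd window side length (default 7).
#' @param edge `"reflect"` (same-size output) or `"valid"` (cropped).
#' @return An object of class `contrast_map` with fields `k` (non-negative
#'   matrix), `window_px` and `border_mask` (logical matrix).
#' @export
spatial_contrast <- function(frame, window_px = 7L, edge = c("reflect", "valid")) {
  stopifnot(inherits(frame, "speckle_frame"))
  edge <- match.arg(edge)
  window_px <- as.integer(window_px)
  if (window_px < 3L || window_px %% 2L == 0L)
    stop("`window_px` must be an odd integer >= 3")
  x <- frame$intensity
  if (nrow(x) < window_px || ncol(x) < window_px)
    stop(sprintf("frame (%d x %d) smaller than the %d x %d window",
                 nrow(x), ncol(x), window_px, window_px))
  half <- (window_px - 1L) %/% 2L
  n <- window_px^2

  if (edge == "reflect") {
    xp <- pad_symmetric(x, half)
  } else {
    xp <- x
  }
  s1 <- box_sum(xp, window_px)
  s2 <- box_sum(xp^2, window_px)
  m1 <- s1 / n
  # population variance; clamp tiny negative rounding residue
  v <- pmax(s2 / n - m1^2, 0)
  k <- matrix(0, nrow(m1), ncol(m1))
  pos <- m1 > 0
  k[pos] <- sqrt(v[pos]) / m1[pos]

  if (edge == "reflect") {
    border <- matrix(FALSE, nrow(x), ncol(x))
    border[c(seq_len(half), nrow(x) - seq_len(half) + 1L), ] <- TRUE
    border[, c(seq_len(half), ncol(x) - seq_len(half) + 1L)] <- TRUE
  } else {
    border <- matrix(FALSE, nrow(m1), ncol(m1))
  }
  border[!pos] <- TRUE
  structure(
    list(k = k, window_px = window_px, border_mask = border),
    class = "contrast_map"
  )
}

# Symmetric (edge-duplicating) padding by p pixels on every side.
pad_symmetric <- function(x, p) {
  if (p == 0L) return(x)
  ri <- c(rev(seq_len(p)), seq_len(nrow(x)), nrow(x) - seq_len(p) + 1L)
  ci <- c(rev(seq_len(p)), seq_len(ncol(x)), ncol(x) - seq_len(p) + 1L)
  x[ri, ci]
}

# Sliding-window sums over all fully contained k x k windows, via a 2D
# cumulative sum with a zero guard row/column.
box_sum <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  cs <- matrix(0, h + 1L, w + 1L)
  cs[-1L, -1L] <- apply(apply(x, 2L, cumsum), 1L, cumsum) |> t()
  oh <- h - k + 1L; ow <- w - k + 1L
  r1 <- seq_len(oh); c1 <- seq_len(ow)
  cs[r1 + k, c1 + k, drop = FALSE] - cs[r1, c1 + k, drop = FALSE] -
    cs[r1 + k, c1, drop = FALSE] + cs[r1, c1, drop = FALSE]
}

#' Convert speckle contrast to laser speckle perfusion units
#'
#' Perfusion is inversely correlated with speckle contrast: the more the
#' red blood cells move during the exposure, the more the speckle blurs
#' and the lower K. This package fixes the convention LSPU = 1/K^2, which
#' is proportional to flow under the Lorentzian decorrelation model in the
#' strong-blur regime; `form = "k1"` gives the plain reciprocal 1/K
#' alternative. Near-zero contrast saturates at `lspu_cap` instead of
#' diverging. Higher LSPU means better perfusion; the units are arbitrary.
#'
#' @param cmap A [spatial_contrast()] result.
#' @param lspu_cap Saturation value substituted where K is (near) zero.
#' @param form `"k2"` for 1/K^2 (default) or `"k1"` for 1/K.
#' @return An object of class `perfusion_map` with fields `lspu`, `valid`
#'   (FALSE on the contrast border mask) and `lspu_cap`.
#' @export
contrast_to_lspu <- function(cmap, lspu_cap = 1e4, form = c("k2", "k1")) {
  stopifnot(inherits(cmap, "contrast_map"))
  form <- match.arg(form)
  if (!is.numeric(lspu_cap) || length(lspu_cap) != 1 || lspu_cap <= 0)
    stop("`lspu_cap` must be a positive scalar")
  k <- cmap$k
  lspu <- matrix(lspu_cap, nrow(k), ncol(k))
  if (form == "k2") {
    ok <- k > sqrt(1 / lspu_cap)
    lspu[ok] <- 1 / k[ok]^2
  } else {
    ok <- k > 1 / lspu_cap
    lspu[ok] <- 1 / k[ok]
  }
  structure(
    list(lspu = lspu, valid = !cmap$border_mask, lspu_cap = lspu_cap),
    class = "perfusion_map"
  )
}

#' Temporal average of perfusion maps
#'
#' Pixelwise mean LSPU across maps from consecutive frames; smooths the
#' per-window estimation noise of a live stream. A pixel is valid in the
#' output only if it is valid in every input.
#'
#' @param maps Non-empty list of [contrast_to_lspu()] results with equal
#'   dimensions.
#' @return A `perfusion_map`.
#' @export
average_perfusion_maps <- function(maps) {
  if (!is.list(maps) || length(maps) < 1)
    stop("`maps` must be a non-empty list of perfusion_map objects")
  if (!all(vapply(maps, inherits, logical(1), "perfusion_map")))
    stop("all elements must be perfusion_map objects")
  d <- dim(maps[[1]]$lspu)
  for (i in seq_along(maps))
    if (!identical(dim(maps[[i]]$lspu), d))
      stop(sprintf("map %d has mismatched dimensions", i))
  acc <- matrix(0, d[1], d[2])
  valid <- matrix(TRUE, d[1], d[2])
  for (m in maps) {
    acc <- acc + m$lspu
    valid <- valid & m$valid
  }
  structure(
    list(lspu = acc / length(maps), valid = valid,
         lspu_cap = maps[[1]]$lspu_cap),
    class = "perfusion_map"
  )
}

#' @export
print.contrast_map <- function(x, ...) {
  interior <- x$k[!x$border_mask]
  cat(sprintf("<contrast_map> %d x %d px, window %d x %d\n",
              nrow(x$k), ncol(x$k), x$window_px, x$window_px))
  if (length(interior))
    cat(sprintf("  interior K: mean %.4f, range [%.4f, %.4f]\n",
                mean(interior), min(interior), max(interior)))
  invisible(x)
}

#' @export
print.perfusion_map <- function(x, ...) {
  v <- x$lspu[x$valid]
  cat(sprintf("<perfusion_map> %d x %d px, %.1f%% valid\n",
              nrow(x$lspu), ncol(x$lspu), 100 * mean(x$valid)))
  if (length(v))
    cat(sprintf("  LSPU (valid): mean %.4g, range [%.4g, %.4g] (cap %g)\n",
                mean(v), min(v), max(v), x$lspu_cap))
  invisible(x)
}
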