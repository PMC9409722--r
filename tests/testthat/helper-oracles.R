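# Independent oracles and shared fixtures for the test suite.

# Naive sliding-window contrast: explicit per-window double loop with
# population standard deviation. Interior pixels only (no padding), so it
# is independent of the running-sums implementation and its edge policy.
naive_contrast_interior <- function(intensity, window_px) {
  half <- (window_px - 1) %/% 2
  h <- nrow(intensity); w <- ncol(intensity)
  k <- matrix(NA_real_, h, w)
  for (r in (half + 1):(h - half)) {
    for (c in (half + 1):(w - half)) {
      win <- intensity[(r - half):(r + half), (c - half):(c + half)]
      mu <- mean(win)
      sigma <- sqrt(sum((win - mu)^2) / length(win))
      k[r, c] <- if (mu > 0) sigma / mu else 0
    }
  }
  k
}

# Closed-form contrast by direct numerical integration of the
# finite-exposure second moment for a Lorentzian field correlation:
# K^2 = beta * (2/T^2) * Int_0^T (T - t) * exp(-2 t / tau) dt.
integrated_contrast <- function(exposure_ms, tau_c_ms, beta = 1) {
  val <- stats::integrate(function(t) (exposure_ms - t) * exp(-2 * t / tau_c_ms),
                          0, exposure_ms, rel.tol = 1e-12)$value
  sqrt(beta * 2 * val / exposure_ms^2)
}

# Interior mean windowed contrast of every frame in a stack.
stack_mean_contrast <- function(stack, window_px = 7) {
  mean(vapply(stack$frames, function(f) {
    cm <- spatial_contrast(f, window_px = window_px)
    mean(cm$k[!cm$border_mask])
  }, numeric(1)))
}

# Default three-band phantom stack used by the end-to-end tests: 192 px
# square, tiers tau_c = 1/5/50 ms, 20 ms exposure at 20 fps, shot +
# read noise. Cached per session because several tests reuse it.
default_phantom_stack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scene <- default_scene(seed = 5)
      phantom <- make_phantom(scene)
      acq <- acquisition_params(n_frames = 16, n_subframes = 16)
      stack <- suppressWarnings(
        generate_dynamic_stack(phantom, acq, noise_params(seed = 2)))
      cache <<- list(scene = scene, phantom = phantom, stack = stack)
    }
    cache
  }
})

# Column positions (0-based, half-integer) of the two ground-truth band
# boundaries of default_scene().
band_boundaries <- function(width_px = 192) {
  c(floor(width_px / 3) - 0.5, floor(2 * width_px / 3) - 0.5)
}
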