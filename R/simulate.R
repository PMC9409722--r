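#' Acquisition parameters for the simulated camera
#'
#' Defaults mirror the clinical acquisition the package emulates: 20 ms
#' exposure at 20 frames per second.
#'
#' @param exposure_ms Exposure time T in milliseconds (default 20).
#' @param frame_rate_fps Frame rate in frames per second (default 20).
#' @param n_frames Number of frames to render.
#' @param n_subframes Temporal sub-samples per exposure used for
#'   finite-exposure integration (>= 8; default 16). Accuracy of the
#'   contrast-vs-exposure match requires the sub-step
#'   `exposure_ms / n_subframes` to be at most `tau_c / 4`; a warning (not
#'   an error) is raised when a scene violates this.
#' @param bit_depth Output bit depth: 8, 12 or 16.
#' @param mean_counts Target mean intensity in digital numbers.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(exposure_ms = 20, frame_rate_fps = 20,
                               n_frames = 1, n_subframes = 16,
                               bit_depth = 16, mean_counts = 10000) {
  if (exposure_ms <= 0 || frame_rate_fps <= 0)
    stop("exposure and frame rate must be positive")
  if (exposure_ms > 1000 / frame_rate_fps)
    stop(sprintf("exposure (%g ms) exceeds the frame interval (%g ms)",
                 exposure_ms, 1000 / frame_rate_fps))
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  if (n_subframes < 8) stop("`n_subframes` must be >= 8")
  if (!bit_depth %in% c(8L, 12L, 16L)) stop("`bit_depth` must be 8, 12 or 16")
  if (mean_counts <= 0) stop("`mean_counts` must be positive")
  structure(
    list(exposure_ms = exposure_ms, frame_rate_fps = frame_rate_fps,
         n_frames = as.integer(n_frames), n_subframes = as.integer(n_subframes),
         bit_depth = as.integer(bit_depth), mean_counts = mean_counts),
    class = "acquisition_params"
  )
}

#' Sensor noise model parameters
#'
#' @param shot_noise Apply Poisson shot noise (photon statistics at unit
#'   gain, i.e. one digital number per photo-electron)?
#' @param read_noise_dn Standard deviation of additive Gaussian read noise,
#'   in digital numbers.
#' @param dark_offset_dn Constant dark offset added to every pixel, in
#'   digital numbers.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(shot_noise = TRUE, read_noise_dn = 2,
                         dark_offset_dn = 0, seed = 1L) {
  if (read_noise_dn < 0) stop("`read_noise_dn` must be >= 0")
  if (dark_offset_dn < 0) stop("`dark_offset_dn` must be >= 0")
  structure(
    list(shot_noise = isTRUE(shot_noise), read_noise_dn = read_noise_dn,
         dark_offset_dn = dark_offset_dn, seed = as.integer(seed)),
    class = "noise_params"
  )
}

#' Noise-free sensor model
#' @return A `noise_params` object with all noise sources disabled.
#' @export
noise_off <- function() noise_params(shot_noise = FALSE, read_noise_dn = 0,
                                     dark_offset_dn = 0)

# --- band-limited circular-Gaussian speckle fields -------------------------

# First half-height point of jinc(x) = 2 J1(x)/x in amplitude-squared:
# |jinc(x_half)|^2 = 1/2. Solved once and cached.
.speckle_cache <- new.env(parent = emptyenv())

jinc_half_point <- function() {
  if (is.null(.speckle_cache$x_half)) {
    jinc <- function(x) 2 * besselJ(x, 1) / x
    .speckle_cache$x_half <- stats::uniroot(
      function(x) jinc(x)^2 - 0.5, c(0.5, 3), tol = 1e-12)$root
  }
  .speckle_cache$x_half
}

# Indices (in an h x w FFT grid) of the circular Fourier aperture whose
# radius yields a given intensity-autocovariance FWHM in pixels. For a
# circular aperture of radius rho0 cycles/pixel the field correlation is
# jinc(2*pi*rho0*r), so FWHM = x_half / (pi * rho0).
aperture_mask_idx <- function(h, w, speckle_size_px) {
  key <- sprintf("ap_%d_%d_%g", h, w, speckle_size_px)
  idx <- .speckle_cache[[key]]
  if (!is.null(idx)) return(idx)
  rho0 <- jinc_half_point() / (pi * speckle_size_px)
  fr <- ((seq_len(h) - 1 + floor(h / 2)) %% h - floor(h / 2)) / h
  fc <- ((seq_len(w) - 1 + floor(w / 2)) %% w - floor(w / 2)) / w
  idx <- which(outer(fr^2, fc^2, "+") <= rho0^2)
  if (length(idx) < 2)
    stop("speckle size too large for the frame: empty Fourier aperture")
  .speckle_cache[[key]] <- idx
  idx
}

# One unit-variance band-limited complex Gaussian field (E[|E|^2] = 1),
# drawn from the current RNG stream.
bandlimited_field <- function(h, w, idx) {
  m <- length(idx)
  fhat <- complex(real = numeric(h * w), imaginary = numeric(h * w))
  fhat[idx] <- complex(real = stats::rnorm(m, sd = sqrt(0.5)),
                       imaginary = stats::rnorm(m, sd = sqrt(0.5)))
  dim(fhat) <- c(h, w)
  stats::fft(fhat, inverse = TRUE) / sqrt(m)
}

#' Generate one static fully developed speckle pattern
#'
#' Synthesizes a single realization of fully developed laser speckle: a
#' circular complex Gaussian random field, band-limited by a circular
#' aperture in the spatial-frequency domain whose radius sets the speckle
#' grain size, squared in magnitude and rescaled to unit mean intensity.
#' For well-resolved speckle and `beta = 1` the ensemble contrast
#' (sd/mean) approaches 1; partial coherence `beta < 1` is modelled by
#' mixing the speckle intensity with a uniform background so that the
#' contrast scales as `sqrt(beta)`.
#'
#' @param height_px,width_px Frame dimensions.
#' @param speckle_size_px Intensity-autocovariance FWHM in pixels (>= 0.5).
#' @param beta Coherence factor in (0, 1].
#' @param seed Integer seed; the pattern is deterministic given the seed.
#' @param exposure_ms Exposure metadata carried by the returned frame.
#' @return A [speckle_frame()] with unit-mean floating-point intensities.
#' @export
generate_static_speckle <- function(height_px, width_px, speckle_size_px = 2,
                                    beta = 1, seed = 1L, exposure_ms = 20) {
  if (height_px < 1 || width_px < 1) stop("frame dimensions must be positive")
  if (speckle_size_px < 0.5) stop("`speckle_size_px` must be >= 0.5")
  if (beta <= 0 || beta > 1) stop("`beta` must be in (0, 1]")
  idx <- aperture_mask_idx(height_px, width_px, speckle_size_px)
  set.seed(seed)
  e <- bandlimited_field(height_px, width_px, idx)
  intens <- Mod(e)^2
  intens <- intens / mean(intens)
  intens <- sqrt(beta) * intens + (1 - sqrt(beta))
  speckle_frame(intens, exposure_ms = exposure_ms, bit_depth = 16L)
}

#' Simulate a dynamic speckle stack from a perfusion phantom
#'
#' Renders the phantom into a stack of finite-exposure speckle frames. The
#' underlying complex field evolves by a first-order autoregressive update
#' with per-pixel correlation `rho = exp(-dt / tau_c)` (Lorentzian field
#' correlation), each innovation being a fresh band-limited speckle field.
#' `n_subframes` instantaneous intensities are averaged per exposure
#' (finite-exposure integration), the result is scaled by the illumination
#' field and `mean_counts`, sensor noise is applied, and frames are
#' quantized to the requested bit depth. Between consecutive exposures the
#' field advances across the dead time in one autoregressive step.
#'
#' @param phantom A [make_phantom()] result.
#' @param acq An [acquisition_params()] object.
#' @param noise A [noise_params()] object; default [noise_off()].
#' @return A [speckle_stack()].
#' @export
generate_dynamic_stack <- function(phantom, acq, noise = noise_off()) {
  stopifnot(inherits(phantom, "perfusion_phantom"),
            inherits(acq, "acquisition_params"),
            inherits(noise, "noise_params"))
  h <- nrow(phantom$tau_c_map)
  w <- ncol(phantom$tau_c_map)
  if (!identical(dim(phantom$illumination_map), c(h, w)))
    stop("illumination map dimensions do not match tau_c map")
  dt_sub <- acq$exposure_ms / acq$n_subframes
  tau_min <- min(phantom$tau_c_map)
  if (dt_sub > tau_min / 4)
    warning(sprintf(paste0(
      "exposure sub-step (%.3g ms) exceeds tau_c/4 for the fastest pixels ",
      "(min tau_c %.3g ms); contrast in those regions is integrated coarsely. ",
      "Increase n_subframes for closer agreement with the closed form."),
      dt_sub, tau_min))
  gap_ms <- 1000 / acq$frame_rate_fps - acq$exposure_ms
  rho_sub <- exp(-dt_sub / phantom$tau_c_map)
  innov_sub <- sqrt(1 - rho_sub^2)
  rho_gap <- exp(-gap_ms / phantom$tau_c_map)
  innov_gap <- sqrt(1 - rho_gap^2)
  sqb <- sqrt(phantom$params$beta)
  gain <- phantom$illumination_map * acq$mean_counts
  full_scale <- 2^acq$bit_depth - 1

  idx <- aperture_mask_idx(h, w, phantom$params$speckle_size_px)
  set.seed(phantom$params$seed)
  e <- bandlimited_field(h, w, idx)
  clean <- vector("list", acq$n_frames)
  for (i in seq_len(acq$n_frames)) {
    acc <- matrix(0, h, w)
    for (s in seq_len(acq$n_subframes)) {
      acc <- acc + Mod(e)^2
      e <- rho_sub * e + innov_sub * bandlimited_field(h, w, idx)
    }
    intens <- acc / acq$n_subframes
    intens <- sqb * intens + (1 - sqb)
    clean[[i]] <- intens * gain
    if (gap_ms > 0)
      e <- rho_gap * e + innov_gap * bandlimited_field(h, w, idx)
  }
  frames <- vector("list", acq$n_frames)
  for (i in seq_len(acq$n_frames)) {
    intens <- clean[[i]]
    if (noise$shot_noise || noise$read_noise_dn > 0 || noise$dark_offset_dn > 0) {
      set.seed(noise$seed + i - 1L)
      intens <- apply_noise(intens, noise)
    }
    intens <- pmin(pmax(round(intens), 0), full_scale)
    frames[[i]] <- speckle_frame(intens, exposure_ms = acq$exposure_ms,
                                 bit_depth = acq$bit_depth)
  }
  speckle_stack(frames, frame_rate_fps = acq$frame_rate_fps)
}

# Noise kernel shared by add_sensor_noise() and the stack generator;
# draws from the current RNG stream, does not clip.
apply_noise <- function(intens, noise) {
  if (noise$shot_noise)
    intens <- matrix(stats::rpois(length(intens), lambda = intens),
                     nrow(intens), ncol(intens))
  if (noise$read_noise_dn > 0)
    intens <- intens + matrix(stats::rnorm(length(intens),
                                           sd = noise$read_noise_dn),
                              nrow(intens), ncol(intens))
  intens + noise$dark_offset_dn
}

#' Apply the sensor noise model to a frame
#'
#' Poisson shot-noise resampling (if enabled), additive Gaussian read
#' noise, and a constant dark offset, followed by clipping at zero and at
#' full scale. Deterministic given `noise$seed`. With every noise source
#' disabled the input frame is returned unchanged.
#'
#' @param frame A [speckle_frame()].
#' @param noise A [noise_params()] object.
#' @return A [speckle_frame()] with the same metadata.
#' @export
add_sensor_noise <- function(frame, noise) {
  stopifnot(inherits(frame, "speckle_frame"), inherits(noise, "noise_params"))
  if (!noise$shot_noise && noise$read_noise_dn == 0 && noise$dark_offset_dn == 0)
    return(frame)
  set.seed(noise$seed)
  intens <- apply_noise(frame$intensity, noise)
  full_scale <- 2^frame$bit_depth - 1
  intens <- pmin(pmax(intens, 0), full_scale)
  speckle_frame(intens, exposure_ms = frame$exposure_ms,
                bit_depth = frame$bit_depth)
}

#' Empirical coherence factor of the simulator at a given speckle size
#'
#' The contrast asymptote actually reached by simulated static speckle
#' falls slightly below the requested `beta` because the sliding-window
#' estimator averages over finitely many speckle grains. This routine
#' measures that asymptote once per configuration by simulating static
#' speckle at `beta = 1`, taking the mean interior windowed contrast, and
#' scaling by the requested `beta`; results are cached for the session.
#' Use the returned value as the `beta` argument of
#' [theoretical_contrast()] and [estimate_tau_c()] when comparing
#' simulated frames against the closed form.
#'
#' @param speckle_size_px Speckle grain FWHM in pixels.
#' @param beta Requested coherence factor (upper bound; attained for
#'   well-resolved speckle).
#' @param window_px Contrast window the calibration should match.
#' @param n_frames Static realizations to average over.
#' @param dim_px Calibration frame side length.
#' @param seed Seed for the calibration realizations.
#' @return Scalar `beta_effective` in (0, beta].
#' @export
calibrate_beta <- function(speckle_size_px, beta = 1, window_px = 7,
                           n_frames = 4, dim_px = 256, seed = 9001L) {
  key <- sprintf("beta_%g_%d_%d_%d_%d", speckle_size_px, window_px,
                 n_frames, dim_px, seed)
  k2 <- .speckle_cache[[key]]
  if (is.null(k2)) {
    ks <- vapply(seq_len(n_frames), function(i) {
      fr <- generate_static_speckle(dim_px, dim_px, speckle_size_px,
                                    beta = 1, seed = seed + i - 1L)
      cm <- spatial_contrast(fr, window_px = window_px)
      mean(cm$k[!cm$border_mask])
    }, numeric(1))
    k2 <- mean(ks)^2
    .speckle_cache[[key]] <- k2
  }
  beta * k2
}
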