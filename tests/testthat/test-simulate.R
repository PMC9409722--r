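test_that("static speckle is deterministic given the seed", {
  f1 <- generate_static_speckle(64, 64, 2, seed = 99)
  f2 <- generate_static_speckle(64, 64, 2, seed = 99)
  expect_identical(f1$intensity, f2$intensity)
  f3 <- generate_static_speckle(64, 64, 2, seed = 100)
  expect_false(identical(f1$intensity, f3$intensity))
})

test_that("fully developed static speckle has near-unit global contrast", {
  fr <- generate_static_speckle(512, 512, speckle_size_px = 4, beta = 1,
                                seed = 42)
  k <- sd(fr$intensity) / mean(fr$intensity)
  expect_gt(k, 0.85)
  expect_lt(k, 1.05)
  expect_equal(mean(fr$intensity), 1, tolerance = 1e-12)  # unit-mean contract
})

test_that("beta scales contrast as sqrt(beta)", {
  f1 <- generate_static_speckle(256, 256, 3, beta = 1, seed = 7)
  f2 <- generate_static_speckle(256, 256, 3, beta = 0.25, seed = 7)
  k1 <- sd(f1$intensity) / mean(f1$intensity)
  k2 <- sd(f2$intensity) / mean(f2$intensity)
  expect_equal(k2 / k1, 0.5, tolerance = 1e-6)
})

test_that("requested speckle size round-trips through the estimator", {
  for (s in c(2, 4)) {
    fr <- generate_static_speckle(256, 256, speckle_size_px = s, seed = 31)
    expect_equal(estimate_speckle_size(fr), s, tolerance = 0.25)
  }
})

test_that("dynamic stack is bit-identical under identical seeds", {
  scene <- scene_params(48, 48, background_tau_c_ms = 10, seed = 3,
                        illumination_falloff = 0.2)
  ph <- make_phantom(scene)
  acq <- acquisition_params(n_frames = 3, n_subframes = 8)
  noise <- noise_params(seed = 17)
  s1 <- generate_dynamic_stack(ph, acq, noise)
  s2 <- generate_dynamic_stack(ph, acq, noise)
  expect_identical(s1, s2)
})

test_that("static limit: enormous tau_c freezes the stack at full contrast", {
  scene <- scene_params(128, 128, background_tau_c_ms = 1e14, beta = 1,
                        illumination_falloff = 0, speckle_size_px = 2, seed = 8)
  ph <- make_phantom(scene)
  acq <- acquisition_params(n_frames = 4, n_subframes = 8)
  st <- generate_dynamic_stack(ph, acq, noise_off())
  i1 <- st$frames[[1]]$intensity
  for (j in 2:4)
    expect_lte(max(abs(st$frames[[j]]$intensity - i1)), 1)  # within 1 DN
  k <- sd(i1) / mean(i1)
  expect_gt(k, 0.85)
  expect_lt(k, 1.05)
})

test_that("mean intensity tracks mean_counts with flat illumination", {
  scene <- scene_params(512, 512, background_tau_c_ms = 20,
                        illumination_falloff = 0, beta = 0.8, seed = 12)
  ph <- make_phantom(scene)
  acq <- acquisition_params(n_frames = 1, n_subframes = 8, mean_counts = 10000)
  st <- generate_dynamic_stack(ph, acq, noise_off())
  expect_equal(mean(st$frames[[1]]$intensity), 10000, tolerance = 0.02)
})

test_that("slower decorrelation gives higher contrast (two-region phantom)", {
  scene <- scene_params(
    96, 96,
    regions = list(scene_region_rect("poor", 0, 96, 48, 96, 100)),
    background_tau_c_ms = 1, illumination_falloff = 0, seed = 21
  )
  ph <- make_phantom(scene)
  acq <- acquisition_params(n_frames = 2, n_subframes = 16)
  st <- suppressWarnings(generate_dynamic_stack(ph, acq, noise_off()))
  cm <- spatial_contrast(st$frames[[1]])
  well <- mean(cm$k[10:86, 10:40])
  poor <- mean(cm$k[10:86, 58:86])
  expect_gt(poor, well)
})

test_that("per-pixel intensity decorrelates as exp(-2 lag / tau_c)", {
  tau <- 5
  scene <- scene_params(64, 64, background_tau_c_ms = tau,
                        illumination_falloff = 0, beta = 1, seed = 14)
  ph <- make_phantom(scene)
  # 1 ms exposure at 1000 fps: frames sample the field nearly instantaneously
  acq <- acquisition_params(exposure_ms = 1, frame_rate_fps = 1000,
                            n_frames = 60, n_subframes = 8,
                            mean_counts = 50000)
  st <- generate_dynamic_stack(ph, acq, noise_off())
  arr <- sapply(st$frames, function(f) as.vector(f$intensity))
  for (lag in 1:3) {
    obs <- mean(sapply(seq_len(60 - lag), function(t)
      cor(arr[, t], arr[, t + lag])))
    expected <- exp(-2 * lag / tau)  # squared field correlation
    expect_equal(obs, expected, tolerance = 0.12)
  }
})

test_that("coarse exposure integration warns but does not fail", {
  scene <- scene_params(32, 32, background_tau_c_ms = 0.5, seed = 1)
  ph <- make_phantom(scene)
  acq <- acquisition_params(n_frames = 1, n_subframes = 8)
  expect_warning(generate_dynamic_stack(ph, acq, noise_off()),
                 "sub-step")
})

test_that("exposure longer than the frame interval is rejected", {
  expect_error(acquisition_params(exposure_ms = 60, frame_rate_fps = 20),
               "frame interval")
})

test_that("sensor noise model honors its contracts", {
  fr <- speckle_frame(matrix(1000, 300, 400), bit_depth = 16)
  # identity when all sources are off
  expect_identical(add_sensor_noise(fr, noise_off()), fr)
  # pure dark offset adds exactly its value
  off <- add_sensor_noise(fr, noise_params(shot_noise = FALSE,
                                           read_noise_dn = 0,
                                           dark_offset_dn = 10))
  expect_true(all(off$intensity == 1010))
  # Poisson shot noise: variance equals the mean
  shot <- add_sensor_noise(speckle_frame(matrix(1000, 400, 400)),
                           noise_params(shot_noise = TRUE, read_noise_dn = 0,
                                        seed = 5))
  expect_equal(var(as.vector(shot$intensity)), 1000, tolerance = 0.1)
  # deterministic given the seed
  shot2 <- add_sensor_noise(speckle_frame(matrix(1000, 400, 400)),
                            noise_params(shot_noise = TRUE, read_noise_dn = 0,
                                         seed = 5))
  expect_identical(shot$intensity, shot2$intensity)
})
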