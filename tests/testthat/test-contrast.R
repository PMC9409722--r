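test_that("a constant frame has zero contrast everywhere", {
  fr <- speckle_frame(matrix(5, 20, 20))
  cm <- spatial_contrast(fr)
  expect_true(all(cm$k == 0))
  expect_equal(cm$window_px, 7L)
})

test_that("3x3 window over 1..9 reproduces the hand-computed contrast", {
  fr <- speckle_frame(matrix(1:9, 3, 3))
  cm <- spatial_contrast(fr, window_px = 3)
  expect_equal(cm$k[2, 2], sqrt(60 / 9) / 5, tolerance = 1e-12)
})

test_that("running-sums contrast matches the naive per-window loop", {
  set.seed(123)
  for (i in 1:3) {
    x <- matrix(runif(64 * 64, 10, 1000), 64, 64)
    cm <- spatial_contrast(speckle_frame(x), window_px = 7)
    ref <- naive_contrast_interior(x, 7)
    interior <- !is.na(ref)
    expect_lt(max(abs(cm$k[interior] - ref[interior]) / ref[interior]), 1e-8)
  }
})

test_that("contrast is invariant to intensity rescaling", {
  set.seed(9)
  x <- matrix(runif(40 * 40, 1, 100), 40, 40)
  k1 <- spatial_contrast(speckle_frame(x))$k
  k2 <- spatial_contrast(speckle_frame(137.5 * x))$k
  expect_lt(max(abs(k1 - k2) / pmax(k1, 1e-12)), 1e-10)
})

test_that("valid edge mode crops to interior windows", {
  set.seed(2)
  x <- matrix(runif(30 * 25, 1, 10), 30, 25)
  full <- spatial_contrast(speckle_frame(x), 7, edge = "reflect")
  valid <- spatial_contrast(speckle_frame(x), 7, edge = "valid")
  expect_equal(dim(valid$k), c(24, 19))
  expect_equal(valid$k, full$k[4:27, 4:22], tolerance = 1e-12)
  expect_false(any(valid$border_mask))
  # reflect border mask flags exactly the 3-px rim
  expect_true(all(full$border_mask[1:3, ]))
  expect_false(any(full$border_mask[4:27, 4:22]))
})

test_that("zero-mean windows yield K = 0 and are flagged", {
  x <- matrix(100, 30, 30)
  x[1:9, 1:9] <- 0
  cm <- spatial_contrast(speckle_frame(x))
  expect_equal(cm$k[5, 5], 0)
  expect_true(cm$border_mask[5, 5])
})

test_that("malformed contrast requests are rejected", {
  fr <- speckle_frame(matrix(1, 10, 10))
  expect_error(spatial_contrast(fr, 4), "odd")
  expect_error(spatial_contrast(speckle_frame(matrix(1, 5, 5)), 7), "smaller")
})

test_that("LSPU conversion follows the 1/K^2 convention with saturation", {
  k <- matrix(c(1, 0.5, 0, 2), 2, 2)
  cm <- structure(list(k = k, window_px = 7L,
                       border_mask = matrix(FALSE, 2, 2)),
                  class = "contrast_map")
  pm <- contrast_to_lspu(cm, lspu_cap = 1e4)
  expect_equal(pm$lspu[1, 1], 1)
  expect_equal(pm$lspu[2, 1], 4)
  expect_equal(pm$lspu[1, 2], 1e4)  # K = 0 saturates, not Inf
  expect_equal(pm$lspu[2, 2], 0.25)
  pm1 <- contrast_to_lspu(cm, form = "k1")
  expect_equal(pm1$lspu[2, 1], 2)
  expect_error(contrast_to_lspu(cm, lspu_cap = -1), "positive")
})

test_that("LSPU is monotone non-increasing in contrast", {
  set.seed(4)
  k <- sort(runif(100, 0, 1.5))
  cm <- structure(list(k = matrix(k, 10, 10), window_px = 7L,
                       border_mask = matrix(FALSE, 10, 10)),
                  class = "contrast_map")
  for (form in c("k2", "k1")) {
    lspu <- contrast_to_lspu(cm, form = form)$lspu
    expect_true(all(diff(as.vector(lspu)) <= 0))
  }
})

test_that("border pixels are invalid in the perfusion map", {
  fr <- speckle_frame(matrix(runif(100, 1, 10), 10, 10))
  pm <- contrast_to_lspu(spatial_contrast(fr))
  expect_false(any(pm$valid[1:3, ]))
  expect_true(all(pm$valid[4:7, 4:7]))
})

test_that("perfusion map averaging is a masked pixelwise mean", {
  mk <- function(val, valid_val = TRUE) {
    structure(list(lspu = matrix(val, 4, 4),
                   valid = matrix(valid_val, 4, 4), lspu_cap = 1e4),
              class = "perfusion_map")
  }
  expect_equal(average_perfusion_maps(list(mk(2)))$lspu, matrix(2, 4, 4))
  avg <- average_perfusion_maps(list(mk(2), mk(4)))
  expect_equal(avg$lspu, matrix(3, 4, 4))
  expect_true(all(avg$valid))
  m3 <- mk(6)
  m3$valid[2, 2] <- FALSE
  avg2 <- average_perfusion_maps(list(mk(2), m3))
  expect_false(avg2$valid[2, 2])
  expect_true(avg2$valid[1, 1])
  bad <- structure(list(lspu = matrix(1, 3, 3), valid = matrix(TRUE, 3, 3),
                        lspu_cap = 1e4), class = "perfusion_map")
  expect_error(average_perfusion_maps(list(mk(1), bad)), "dimensions")
})
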