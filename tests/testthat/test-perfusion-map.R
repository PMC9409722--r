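make_pmap <- function(lspu, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(lspu), ncol(lspu))
  structure(list(lspu = lspu, valid = valid, lspu_cap = 1e4),
            class = "perfusion_map")
}

test_that("underexposure mask follows the window-mean threshold", {
  dark <- speckle_frame(matrix(0, 20, 20))
  expect_false(any(mask_underexposed(dark)))
  bright <- speckle_frame(matrix(65535, 20, 20))
  expect_true(all(mask_underexposed(bright)))
  expect_error(mask_underexposed(bright, threshold_frac = 1.5), "0, 1")
})

test_that("strong illumination falloff masks the corners, not the center", {
  ph <- make_phantom(scene_params(96, 96, illumination_falloff = 0.9))
  fr <- speckle_frame(round(ph$illumination_map * 5000), bit_depth = 16)
  valid <- mask_underexposed(fr)  # default threshold: 2% of 65535 = 1310.7 DN
  expect_false(valid[1, 1])
  expect_false(valid[96, 96])
  expect_true(valid[48, 48])
})

test_that("relative perfusion normalizes by the reference ROI statistic", {
  uni <- make_pmap(matrix(8, 30, 30))
  rel <- relative_perfusion(uni, roi_rect(0, 10, 0, 10))
  expect_true(all(rel$percent == 100))
  expect_equal(rel$reference_value, 8)
  # pixel at half the reference
  lspu <- matrix(10, 30, 30)
  lspu[15, 15] <- 5
  rel2 <- relative_perfusion(make_pmap(lspu), roi_rect(0, 10, 0, 10))
  expect_equal(rel2$percent[15, 15], 50)
  # mean statistic
  rel3 <- relative_perfusion(make_pmap(lspu), roi_rect(0, 30, 0, 30),
                             statistic = "mean")
  expect_equal(rel3$reference_value, mean(lspu))
})

test_that("a reference ROI in a masked corner is rejected", {
  valid <- matrix(TRUE, 30, 30)
  valid[1:12, 1:12] <- FALSE
  pm <- make_pmap(matrix(5, 30, 30), valid)
  expect_error(relative_perfusion(pm, roi_rect(0, 10, 0, 10)), "valid pixels")
})

test_that("ROI shapes rasterize correctly", {
  m <- roi_mask(roi_rect(0, 5, 0, 4), c(10, 10))
  expect_equal(sum(m), 20)
  e <- roi_mask(roi_ellipse(5, 5, 3, 3), c(11, 11))
  expect_true(e[6, 6])           # center
  expect_false(e[1, 1])
  expect_equal(sum(e), sum(outer((0:10 - 5)^2, (0:10 - 5)^2, "+") <= 9))
  p <- roi_mask(roi_polygon(rbind(c(0, 0), c(0, 8), c(8, 8), c(8, 0))),
                c(10, 10))
  expect_true(p[4, 4])
  expect_false(p[10, 10])
  expect_error(roi_mask(roi_rect(50, 60, 50, 60), c(10, 10)), "intersect")
})

test_that("classification partitions every pixel exactly once", {
  percent <- matrix(c(100, 45, 30, 5), 2, 2)
  valid <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  rel <- structure(list(percent = percent, reference_value = 10,
                        valid = valid), class = "relative_perfusion_map")
  lab <- classify_regions(rel, t_marginal = 18, t_well = 55)
  expect_equal(lab$labels[1, 1], "well")      # 100 >= 55
  expect_equal(lab$labels[2, 1], "marginal")  # 18 <= 45 < 55
  expect_equal(lab$labels[1, 2], "marginal")  # 30
  expect_equal(lab$labels[2, 2], "invalid")   # masked
  expect_true(all(lab$labels %in% c("well", "marginal", "poor", "invalid")))
  expect_identical(lab$labels == "invalid", !valid)
  # boundary semantics: percent exactly at a threshold belongs upward
  rel$percent[1, 1] <- 55
  expect_equal(classify_regions(rel)$labels[1, 1], "well")
  expect_error(classify_regions(rel, t_marginal = 60, t_well = 55), "t_well")
})

test_that("raising t_well never converts poor pixels to well", {
  set.seed(10)
  rel <- structure(list(percent = matrix(runif(400, 0, 120), 20, 20),
                        reference_value = 1,
                        valid = matrix(TRUE, 20, 20)),
                   class = "relative_perfusion_map")
  lab1 <- classify_regions(rel, 18, 55)$labels
  lab2 <- classify_regions(rel, 18, 80)$labels
  expect_true(all(lab2[lab1 == "poor"] == "poor"))
  expect_true(all(lab1[lab2 == "well"] == "well"))
})

test_that("demarcation traces the boundary between two half-planes", {
  labels <- matrix("poor", 40, 60)
  labels[, 31:60] <- "well"
  lm <- structure(list(labels = labels, t_marginal = 18, t_well = 55),
                  class = "label_map")
  contours <- extract_demarcation(lm)
  expect_equal(length(contours), 1)
  pts <- contours[[1]]
  expect_true(all(pts[, "col"] == 30 - 0.5))   # 0-based boundary column
  expect_equal(nrow(pts), 41)                  # spans the full height
  # uniform map: no contours
  uni <- structure(list(labels = matrix("well", 10, 10), t_marginal = 18,
                        t_well = 55), class = "label_map")
  expect_equal(extract_demarcation(uni), list())
})

test_that("contours never pass through invalid regions", {
  labels <- matrix("poor", 20, 30)
  labels[, 16:30] <- "well"
  labels[, 14:17] <- "invalid"   # invalid stripe swallows the boundary
  lm <- structure(list(labels = labels, t_marginal = 18, t_well = 55),
                  class = "label_map")
  contours <- extract_demarcation(lm)
  expect_equal(length(contours), 0)
  # boundary touching invalid only at the ends still avoids it
  labels2 <- matrix("poor", 20, 30)
  labels2[, 16:30] <- "well"
  labels2[1:5, ] <- "invalid"
  lm2 <- structure(list(labels = labels2, t_marginal = 18, t_well = 55),
                   class = "label_map")
  pts2 <- do.call(rbind, extract_demarcation(lm2))
  expect_true(all(pts2[, "row"] >= 4.5))
})
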