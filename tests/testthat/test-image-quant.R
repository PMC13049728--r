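test_that("CTCF follows the printed formula exactly", {
  # integrated density 50,000 over 2,000 px with background mean 10
  img <- matrix(10, 60, 60)
  lab <- matrix(0L, 60, 60)
  roi <- cbind(rep(1:40, 50), rep(1:50, each = 40))
  lab[roi] <- 1L
  img[roi] <- 25 # 2000 px x 25 = 50,000 integrated density
  bg <- matrix(FALSE, 60, 60); bg[45:60, 45:60] <- TRUE
  res <- ctcf(roi_set(img, lab, bg))
  expect_equal(res$integrated_density, 50000)
  expect_equal(res$area, 2000)
  expect_equal(res$background_mean, 10)
  expect_equal(res$ctcf, 30000)
  expect_equal(res$ctcf, res$integrated_density - res$area * res$background_mean)
})

test_that("CTCF is invariant under additive offset and linear under gain", {
  sim <- simulate_fluor_image(sim_config(seed = 41))
  base <- ctcf(sim$rois)
  up <- sim$rois
  up$image <- up$image + 37.5
  shifted <- ctcf(up)
  expect_equal(shifted$ctcf, base$ctcf, tolerance = 1e-9)
  gained <- sim$rois
  gained$image <- gained$image * 2.5
  expect_equal(ctcf(gained)$ctcf, 2.5 * base$ctcf, tolerance = 1e-9)
})

test_that("planted per-cell totals are recovered on zero-noise images", {
  sim <- simulate_fluor_image(sim_config(seed = 42))
  res <- ctcf(sim$rois)
  expect_equal(res$ctcf, sim$truth$totals, tolerance = 1e-3)
  # per-ROI background averaging agrees here (flat background)
  res2 <- ctcf(sim$rois, background = "per_roi")
  expect_equal(res2$ctcf, res$ctcf, tolerance = 1e-9)
})

test_that("ROI sets are validated", {
  img <- matrix(1, 10, 10)
  lab <- matrix(0L, 10, 10); lab[2:4, 2:4] <- 1L
  bad_bg <- matrix(FALSE, 10, 10); bad_bg[3, 3] <- TRUE
  expect_error(roi_set(img, lab, bad_bg), "disjoint")
  bg <- matrix(FALSE, 10, 10); bg[8:10, 8:10] <- TRUE
  expect_error(ctcf(roi_set(img, matrix(0L, 10, 10), bg)), "no cell ROI")
  empty_bg <- matrix(FALSE, 10, 10)
  expect_error(ctcf(roi_set(img, lab, empty_bg)), "empty background")
})

test_that("wound segmentation recovers a planted low-texture stripe", {
  set.seed(43)
  img <- matrix(runif(120 * 160, 0, 1), 120, 160)
  stripe <- 70:95
  img[, stripe] <- 0.5
  mask <- segment_wound(img)
  # the mask is the stripe up to a 2 px boundary band
  core <- matrix(FALSE, 120, 160); core[, (min(stripe) + 2):(max(stripe) - 2)] <- TRUE
  halo <- matrix(FALSE, 120, 160); halo[, (min(stripe) - 8):(max(stripe) + 8)] <- TRUE
  expect_gt(mean(mask[core]), 0.95)
  expect_true(all(!mask[!halo]))
  # invariant under intensity offset
  mask2 <- segment_wound(img + 5)
  expect_identical(mask, mask2)
})

test_that("a fully textured frame yields an empty mask with a warning", {
  set.seed(44)
  img <- matrix(runif(100 * 100), 100, 100)
  expect_warning(mask <- segment_wound(img), "empty mask|no low-texture")
  expect_equal(sum(mask), 0)
})

test_that("wound area shrinks across a synthetic closing series", {
  # frames 0-6 h: the open stripe stays wider than the texture window
  sim <- simulate_scratch(sim_config(seed = 45,
                                     scratch = list(times = 0:6)))
  set.seed(46)
  areas <- vapply(sim$series$open_masks, function(open) {
    img <- matrix(runif(length(open)), nrow(open), ncol(open))
    img[open] <- 0.5
    sum(segment_wound(img, min_area = 50))
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("gap closure follows its definition", {
  m0 <- matrix(FALSE, 100, 200); m0[, 51:150] <- TRUE # 10,000 px
  m9 <- matrix(FALSE, 100, 200); m9[, 88:112] <- TRUE # 2,500 px
  gc <- gap_closure(scratch_series(c(0, 9), list(m0, m9)))
  expect_equal(gc$closure_pct, c(0, 75))
  # no migration
  gc0 <- gap_closure(scratch_series(c(0, 3, 6), list(m0, m0, m0)))
  expect_equal(gc0$closure_pct, c(0, 0, 0))
  empty <- matrix(FALSE, 100, 200)
  expect_error(gap_closure(scratch_series(c(0, 1), list(empty, empty))),
               "initial open area")
  # non-nested masks warn
  shifted <- m9; shifted[, 180:190] <- TRUE
  expect_warning(gap_closure(scratch_series(c(0, 9), list(m0, shifted))),
                 "not nested")
})

test_that("a constant-rate series closes linearly at the planted rate", {
  sim <- simulate_scratch(sim_config(seed = 47))
  gc <- gap_closure(sim$series)
  expect_equal(gc$closure_pct[1], 0)
  fit <- lm(closure_pct ~ time_h, data = gc)
  expect_lt(abs(coef(fit)[2] / sim$truth$rate_pct_per_h - 1), 0.02)
  expect_true(all(diff(gc$closure_pct) >= 0))
})

test_that("scratch series validate their time grid", {
  m <- matrix(TRUE, 4, 4)
  expect_error(scratch_series(c(1, 2), list(m, m)), "must be 0")
  expect_error(scratch_series(c(0, 0), list(m, m)), "strictly increasing")
  expect_error(scratch_series(c(0, 1), list(m, matrix(TRUE, 5, 5))),
               "identical|dim")
})

test_that("TIFF round trip preserves masks and relative intensities", {
  sim <- simulate_scratch(sim_config(seed = 48))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(lapply(sim$series$open_masks, function(m) m * 1), path)
  back <- read_image_tiff(path)
  expect_length(back, length(sim$series$open_masks))
  for (i in seq_along(back))
    expect_equal(back[[i]] > 0.5, unname(sim$series$open_masks[[i]]))
})
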