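# hand-built map of synthetic pixel fits, for aggregation tests that do not
# need the curve-fitting stages
fake_map <- function(E, L = NA_real_, grid = c(4L, 5L),
                     cell = NULL, central = NULL) {
  pixels <- vector("list", prod(grid))
  dim(pixels) <- grid
  Em <- matrix(E, grid[1], grid[2])
  Lm <- matrix(L, grid[1], grid[2])
  if (is.null(cell)) cell <- matrix(TRUE, grid[1], grid[2])
  if (is.null(central)) central <- central_region(cell, 0.5)
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) {
    if (!cell[i, j]) next
    hz <- structure(list(E = Em[i, j], converged = TRUE), class = "hertz_fit")
    pixels[[i, j]] <- structure(
      list(hertz = hz, brush_detected = !is.na(Lm[i, j]),
           brush = if (!is.na(Lm[i, j]))
             structure(list(detected = TRUE, L = Lm[i, j]),
                       class = "brush_fit"),
           quality_flags = character()),
      class = "curve_decomposition")
  }
  structure(list(header = map_header(grid_shape = grid), pixels = pixels,
                 cell_mask = cell, central_mask = central,
                 mode = "decompose"),
            class = "force_map")
}

test_that("a uniform map summarises to the constant field", {
  m <- fake_map(E = 2000, L = 300)
  s <- summarize_cell(m)
  expect_equal(s$E_whole, 2000)
  expect_equal(s$E_central, 2000)
  expect_equal(s$L_whole, 300)
  expect_equal(s$L_central, 300)
  expect_equal(s$n_valid, 20)
})

test_that("regional contrast is reflected in the summaries", {
  grid <- c(7L, 7L)
  cell <- matrix(TRUE, 7, 7)
  central <- central_region(cell, 0.5)
  Lm <- matrix(400, 7, 7)
  Lm[central] <- 200
  m <- fake_map(E = 2000, L = Lm, grid = grid, cell = cell,
                central = central)
  s <- summarize_cell(m)
  expect_equal(s$L_central, 200)
  expect_gte(s$L_whole, 200)
  expect_lte(s$L_whole, 400)
})

test_that("summaries are invariant to pixel traversal order", {
  set.seed(5)
  Em <- matrix(rlnorm(20, log(2000), 0.3), 4, 5)
  m <- fake_map(E = Em)
  s <- summarize_cell(m)
  # transpose the whole map: same multiset of pixels per region
  mt <- fake_map(E = t(Em), grid = c(5L, 4L),
                 cell = t(m$cell_mask), central = t(m$central_mask))
  st <- summarize_cell(mt)
  expect_equal(s$E_whole, st$E_whole)
  expect_equal(s$E_central, st$E_central)
})

test_that("regions with too few valid pixels are reported absent", {
  cell <- matrix(FALSE, 4, 5); cell[1, 1:3] <- TRUE
  m <- fake_map(E = 2000, cell = cell, central = matrix(FALSE, 4, 5))
  s <- summarize_cell(m)
  expect_true(is.na(s$E_whole)) # 3 valid < 4
  expect_true(is.na(s$E_central)) # empty mask
  expect_gt(length(s$reasons), 0)
})

test_that("percent reduction follows its definition", {
  expect_equal(percent_reduction(10000, 4000), 60)
  expect_equal(percent_reduction(1234, 1234), 0)
  expect_error(percent_reduction(0, 10), "positive")
  expect_error(percent_reduction(-5, 10), "positive")
  s1 <- summarize_cell(fake_map(E = 10000))
  s2 <- summarize_cell(fake_map(E = 4000))
  expect_equal(percent_reduction(s1, s2), 60)
  # swapping before/after maps r to -r/(1 - r/100)
  r <- percent_reduction(10000, 4000)
  expect_equal(percent_reduction(4000, 10000), -r / (1 - r / 100),
               tolerance = 1e-12)
})

test_that("group comparison wraps the standard tests", {
  set.seed(9)
  a <- rnorm(12, 2000, 150)
  b <- rnorm(12, 2000 + 3 * 150, 150)
  gk <- compare_groups(c(a, b), rep(c("x", "y"), each = 12))
  expect_lt(gk$p_value, 0.001)
  gt <- compare_groups(c(a, b), rep(c("x", "y"), each = 12), test = "t")
  expect_lt(gt$p_value, 0.001)
  # identical samples under two labels: rank statistic exactly zero
  g0 <- compare_groups(c(a, a), rep(c("x", "y"), each = 12))
  expect_equal(g0$statistic, 0, tolerance = 1e-12)
  expect_error(compare_groups(a, rep("x", 12)), "2 groups")
  expect_error(compare_groups(c(a[1:2], b[1:2]), c("x", "x", "y", "y")),
               "3 observations")
  # summaries with a field selector work too
  ss <- c(lapply(a, function(e) summarize_cell(fake_map(E = e))),
          lapply(b, function(e) summarize_cell(fake_map(E = e))))
  gs <- compare_groups(ss, rep(c("x", "y"), each = 12))
  expect_equal(gs$p_value, gk$p_value)
})

test_that("central region halves the mask around its centroid", {
  cell <- matrix(FALSE, 11, 11)
  cell[3:9, 2:10] <- TRUE
  ctr <- central_region(cell, 0.5)
  expect_true(all(cell[ctr]))
  expect_equal(sum(ctr), round(0.5 * sum(cell)))
  # all retained pixels are closer to the centroid than all dropped ones
  idx <- which(cell, arr.ind = TRUE)
  cen <- colMeans(idx)
  d2 <- (idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2
  kept <- ctr[cell]
  expect_lte(max(d2[kept]), min(d2[!kept]) + 1e-9)
})

test_that("fitted phantom maps recover planted regional ordering", {
  sim <- simulate_map(sim_config(seed = 61,
                                 map = list(L_central = 200,
                                            L_periphery = 400,
                                            noise_sd = 3)))
  fm <- fit_map(sim$curves, sim$header, sim$cell_mask, sim$central_mask)
  s <- summarize_cell(fm)
  expect_lt(abs(s$L_central / 200 - 1), 0.15)
  expect_gt(s$L_whole, s$L_central)
  expect_false(any(fm$central_mask & !fm$cell_mask))
})
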