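one_px <- function(v) matrix(v, 1, 1)
full_mask <- function(h = 1, w = 1) matrix(TRUE, h, w)
`%within%` <- function(x, rng) x >= rng[1] & x <= rng[2]

test_that("indicator arithmetic matches the defining formulas", {
  expect_equal(compute_fvfm(one_px(600), one_px(3000), full_mask())$values[1, 1],
               0.8)
  expect_equal(compute_fvfm(one_px(1000), one_px(1000), full_mask())$values[1, 1],
               0.0)
  expect_equal(compute_phipsii(one_px(1500), one_px(2500), full_mask())$values[1, 1],
               0.4)
  expect_equal(compute_phipsii(one_px(1260), one_px(1800), full_mask())$values[1, 1],
               0.3)
  expect_equal(compute_phipsii(one_px(1800), one_px(1800), full_mask())$values[1, 1],
               0.0)
  expect_equal(compute_ratio_550_510(one_px(160), one_px(100), full_mask())$values[1, 1],
               1.6)
  expect_equal(compute_ratio_550_510(one_px(75), one_px(75), full_mask())$values[1, 1],
               1.0)
})

test_that("degenerate denominators are undefined, negatives clamped and counted", {
  # background pixel with Fm = 0 next to a real plant pixel
  fo <- matrix(c(600, 0), 1, 2)
  fm <- matrix(c(3000, 0), 1, 2)
  m <- compute_fvfm(fo, fm, full_mask(1, 2))
  expect_true(is.na(m$values[1, 2]))
  expect_equal(m$values[1, 1], 0.8)

  r <- compute_ratio_550_510(matrix(c(160, 80), 1, 2), matrix(c(100, 0), 1, 2),
                             full_mask(1, 2))
  expect_true(is.na(r$values[1, 2]))

  # noise-induced Fo > Fm clamps to 0 and is counted
  neg <- compute_fvfm(matrix(c(3100, 600), 1, 2), matrix(c(3000, 3000), 1, 2),
                      full_mask(1, 2))
  expect_equal(neg$values[1, 1], 0)
  expect_identical(neg$n_clamped, 1L)

  expect_error(compute_fvfm(matrix(1, 2, 2), matrix(1, 3, 3), full_mask(3, 3)),
               "co-registered")
})

test_that("summaries use population std and interpolated quartiles", {
  const <- compute_fvfm(matrix(600, 4, 4), matrix(3000, 4, 4), full_mask(4, 4))
  s <- summarize_map(const, day = 2)
  expect_equal(s$mean, 0.8)
  expect_equal(s$std, 0)
  expect_equal(c(s$q1, s$median, s$q3), c(0.8, 0.8, 0.8))
  expect_identical(s$day, 2L)
  expect_identical(s$n_pixels, 16L)

  # 50 px at 0.2 and 50 at 0.8: mean 0.5, population sd 0.3
  fo <- matrix(c(rep(2400, 50), rep(600, 50)), 10, 10)
  fm <- matrix(3000, 10, 10)
  s2 <- summarize_map(compute_fvfm(fo, fm, full_mask(10, 10)))
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$std, 0.3)
  expect_true(s2$q1 <= s2$median && s2$median <= s2$q3)

  empty <- compute_fvfm(matrix(0, 2, 2), matrix(0, 2, 2),
                        matrix(FALSE, 2, 2))
  expect_error(summarize_map(empty), class = "fluoroscan_empty_mask")
})

test_that("healthy fixtures summarise inside the published normal ranges", {
  for (seed in 1:10) {
    f <- healthy_field(seed = seed)
    stk <- render_stack(f, imaging_model(), seed = seed)
    s <- summarize_maps(compute_indicator_maps(stk, truth_mask(f)), day = 1)
    expect_true(dplyr::filter(s, indicator == "fvfm")$mean %within%
                  c(0.78, 0.82))
    expect_true(dplyr::filter(s, indicator == "phipsii")$mean %within%
                  c(0.38, 0.42))
    expect_gte(dplyr::filter(s, indicator == "r550_510")$mean, 1.5)
  }
})

test_that("pseudo-color rendering is deterministic with fixed scales", {
  map <- compute_fvfm(matrix(c(450, 1800, 0, 3000), 2, 2),
                      matrix(c(3000, 3000, 0, 3000), 2, 2),
                      full_mask(2, 2))
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_pseudocolor(map, p1)
  render_pseudocolor(map, p2)
  expect_identical(readBin(p1, "raw", 1e6), readBin(p2, "raw", 1e6))
  img <- png::readPNG(p1)
  # undefined pixel is black
  expect_equal(unname(img[1, 2, ]), c(0, 0, 0))
  # value at the scale maximum maps to the top colormap entry
  top <- grDevices::col2rgb(grDevices::hcl.colors(256, "Viridis")[256]) / 255
  expect_equal(unname(img[1, 1, ]), unname(top[, 1]), tolerance = 0.01)
})

test_that("autoplot and trajectory plots build without evaluation errors", {
  f <- healthy_field(seed = 1)
  stk <- render_stack(f, imaging_model(), seed = 1)
  maps <- compute_indicator_maps(stk, truth_mask(f))
  expect_s3_class(ggplot2::autoplot(maps$fvfm), "ggplot")
  s <- dplyr::bind_rows(summarize_maps(maps, day = 1),
                        summarize_maps(maps, day = 2))
  expect_s3_class(plot_trajectory(s), "ggplot")
})
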