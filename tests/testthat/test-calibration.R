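test_that("drought curve reproduces its working anchors and interpolates linearly", {
  curve <- drought_curve()
  expect_identical(phipsii_at(curve, -0.5), 0.43)
  expect_identical(phipsii_at(curve, -1.0), 0.28)
  expect_identical(phipsii_at(curve, -2.5), 0.21)
  # midpoint of the first (steep) segment
  expect_equal(phipsii_at(curve, -0.75), 0.355)
  expect_equal(water_potential_from_phipsii(curve, 0.28), -1.0)
  expect_equal(water_potential_from_phipsii(curve, 0.355), -0.75)
})

test_that("drought curve clamps out-of-range queries with a warning", {
  curve <- drought_curve()
  expect_warning(v <- phipsii_at(curve, -3.5), "clamped")
  expect_identical(v, 0.21)
  expect_warning(wp <- water_potential_from_phipsii(curve, 0.50), "clamped")
  expect_identical(wp, -0.5)
})

test_that("drought curve is strictly decreasing and inverts to 1e-9", {
  curve <- drought_curve()
  grid <- seq(-2.5, -0.5, by = 0.01)   # wetter left to right
  vals <- phipsii_at(curve, grid)
  expect_true(all(diff(vals) > 0))
  round_trip <- phipsii_at(curve, water_potential_from_phipsii(curve, vals))
  expect_lt(max(abs(round_trip - vals)), 1e-9)
  expect_error(drought_curve(tibble::tibble(water_potential = c(-1, -0.5),
                                            phipsii = c(0.3, 0.4))),
               "decreasing")
})

test_that("nitrogen calibration is ordinary least squares with honest R^2", {
  exact <- tibble::tibble(total_n = c(10, 20, 30, 40),
                          fvfm = 0.5 + 0.006 * c(10, 20, 30, 40))
  fit <- suppressWarnings(fit_nitrogen_calibration(exact))  # perfect fit
  expect_equal(fit$r_squared, 1.0)
  expect_equal(fit$slope, 0.006)
  expect_equal(fit$intercept, 0.5)
  expect_equal(predict(fit, 25), 0.65)
  expect_equal(estimate_total_nitrogen(fit, 0.65), 25)

  expect_error(fit_nitrogen_calibration(
    tibble::tibble(total_n = rep(20, 5), fvfm = runif(5))),
    class = "fluoroscan_degenerate_fit")
  expect_error(fit_nitrogen_calibration(exact[1:2, ]), "at least 3")
})

test_that("linear-fit parameter recovery stays within 3 standard errors", {
  pairs <- simulate_nitrogen_pairs(n = 60, seed = 21)
  fit <- fit_nitrogen_calibration(pairs)
  se <- tidy(fit)$std.error
  expect_lt(abs(fit$slope - 0.006), 3 * se[2])
  expect_lt(abs(fit$intercept - 0.50), 3 * se[1])
})

test_that("R^2 is invariant to affine rescaling of the regressor", {
  pairs <- simulate_nitrogen_pairs(n = 40, seed = 3)
  r2 <- fit_nitrogen_calibration(pairs)$r_squared
  rescaled <- dplyr::mutate(pairs, total_n = 100 * total_n - 17)
  expect_equal(fit_nitrogen_calibration(rescaled)$r_squared, r2,
               tolerance = 1e-12)
})

test_that("tidy and glance expose the fit in broom form", {
  fit <- fit_nitrogen_calibration(simulate_nitrogen_pairs())
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "total_n"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_identical(gl$n, 60L)
  expect_true(gl$r.squared > 0 && gl$r.squared < 1)
})

test_that("Nessler assay recovers nitrogen through the dilution bookkeeping", {
  # ideal linear standards: OD = 0.05 + 0.05 * mL
  od <- 0.05 + 0.05 * c(0, 2, 4, 6, 8, 10)

  # sample at the blank's OD carries no nitrogen
  blank <- nessler_assay(od, sample_od480 = od[1])
  expect_equal(nessler_total_nitrogen(blank), 0)

  # sample at the 5 mL-equivalent midpoint: half the top-standard N in the
  # 1 mL aliquot, scaled by 50 mL digest / 0.1 g dry weight
  mid <- nessler_assay(od, sample_od480 = 0.05 + 0.05 * 5)
  n_top_mg <- 10 * 10 / 1000 * (2 * 14.007 / 132.14)
  expected <- (n_top_mg / 2) * 50 / 1 / 0.1
  expect_equal(nessler_total_nitrogen(mid), expected)

  # extrapolation beyond the top standard is refused
  high <- nessler_assay(od, sample_od480 = 1.1 * max(od))
  expect_error(nessler_total_nitrogen(high),
               class = "fluoroscan_extrapolation")

  # non-monotone standards draw a warning but still fit
  wobble <- nessler_assay(c(0.05, 0.16, 0.14, 0.35, 0.45, 0.55),
                          sample_od480 = 0.30)
  expect_warning(nessler_total_nitrogen(wobble), "monotone")
})

test_that("calibration plots build", {
  expect_s3_class(ggplot2::autoplot(drought_curve()), "ggplot")
  fit <- fit_nitrogen_calibration(simulate_nitrogen_pairs())
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
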