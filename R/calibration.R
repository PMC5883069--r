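#' PhiPSII vs leaf water potential calibration curve
#'
#' The relationship between the operating PSII efficiency and leaf water
#' potential is non-linear: PhiPSII is sensitive while drought is mild
#' (falling from 0.43 to 0.28 between -0.5 and -1.0 MPa) and nearly flat once
#' water deficiency passes the threshold (only 0.28 to 0.21 between -1.0 and
#' -2.5 MPa). The operational curve is a monotone piecewise-linear
#' interpolation through these working anchors.
#'
#' @param anchors Tibble/data frame with columns `water_potential` (MPa,
#'   strictly decreasing) and `phipsii` (strictly decreasing along the
#'   anchors).
#' @return An object of class `drought_curve`.
#' @export
#' @examples
#' phipsii_at(drought_curve(), c(-0.5, -1, -2.5))
drought_curve <- function(anchors = tibble::tibble(
                            water_potential = c(-0.5, -1.0, -2.5),
                            phipsii = c(0.43, 0.28, 0.21))) {
  anchors <- tibble::as_tibble(anchors)
  if (nrow(anchors) < 2) abort("need at least two anchors.")
  if (any(diff(anchors$water_potential) >= 0)) {
    abort("anchor water potentials must be strictly decreasing.")
  }
  if (any(diff(anchors$phipsii) >= 0)) {
    abort("anchor PhiPSII values must be strictly decreasing.")
  }
  structure(list(anchors = anchors), class = "drought_curve")
}

#' @export
print.drought_curve <- function(x, ...) {
  cat("<drought_curve> PhiPSII ~ water potential, anchors:\n")
  print(as.data.frame(x$anchors), row.names = FALSE)
  invisible(x)
}

#' Evaluate the drought curve at a water potential
#'
#' Piecewise-linear interpolation through the anchors; outside the anchored
#' range the endpoint value is returned with a warning (the calibration has
#' no support there).
#'
#' @param curve A [drought_curve()].
#' @param water_potential Water potential(s), MPa (negative; drier is more
#'   negative).
#' @return PhiPSII value(s).
#' @export
phipsii_at <- function(curve, water_potential) {
  if (!inherits(curve, "drought_curve")) abort("`curve` must be a drought_curve.")
  a <- curve$anchors
  rng <- range(a$water_potential)
  if (any(water_potential < rng[1] | water_potential > rng[2])) {
    warn(sprintf("water potential outside the calibrated range [%g, %g] MPa; clamped.",
                 rng[1], rng[2]))
  }
  approx(a$water_potential, a$phipsii, xout = water_potential, rule = 2)$y
}

#' Invert the drought curve: water potential from PhiPSII
#'
#' Exact inverse of [phipsii_at()] on the calibrated range; PhiPSII values
#' outside the anchored range are clamped to the endpoints with a warning.
#'
#' @param curve A [drought_curve()].
#' @param phipsii PhiPSII value(s).
#' @return Water potential(s), MPa.
#' @export
water_potential_from_phipsii <- function(curve, phipsii) {
  if (!inherits(curve, "drought_curve")) abort("`curve` must be a drought_curve.")
  a <- curve$anchors
  rng <- range(a$phipsii)
  if (any(phipsii < rng[1] | phipsii > rng[2])) {
    warn(sprintf("PhiPSII outside the calibrated range [%g, %g]; clamped.",
                 rng[1], rng[2]))
  }
  approx(a$phipsii, a$water_potential, xout = phipsii, rule = 2)$y
}

#' Simulate the nutrition calibration dataset
#'
#' The nutrition preset of the synthetic generator: paired observations of
#' leaf total nitrogen content and Fv/Fm from plants grown across nitrogen
#' strengths. Fv/Fm responds linearly to total nitrogen (slope 0.006 per
#' mg N g^-1 dw, intercept 0.50 over a 10-50 mg g^-1 range, spanning roughly
#' 0.56-0.80); the Gaussian noise sd (0.038) is calibrated so the default
#' dataset (n = 60, seed 7) reproduces the observed coefficient of
#' determination of 0.85 -- a calibrated-to-observation preset, not a noise
#' level derived from first principles.
#'
#' @param n Number of (total_n, fvfm) pairs.
#' @param seed Seed for sampling.
#' @param slope,intercept Linear relation, Fv/Fm per (mg N g^-1 dw).
#' @param n_range Range of total nitrogen content, mg N g^-1 dw.
#' @param noise_sd Gaussian noise sd on Fv/Fm.
#' @return Tibble with columns `total_n` (mg N g^-1 dw) and `fvfm`.
#' @export
simulate_nitrogen_pairs <- function(n = 60L, seed = 7L, slope = 0.006,
                                    intercept = 0.50, n_range = c(10, 50),
                                    noise_sd = 0.038) {
  set.seed(seed)
  total_n <- runif(n, n_range[1], n_range[2])
  fvfm <- intercept + slope * total_n + rnorm(n, 0, noise_sd)
  tibble::tibble(total_n = total_n, fvfm = fvfm)
}

#' Fit the Fv/Fm vs total nitrogen linear calibration
#'
#' Ordinary least squares of Fv/Fm on total nitrogen content; Fv/Fm reflects
#' nitrogen content linearly, so the fit's coefficient of determination
#' summarises calibration quality.
#'
#' @param pairs Data frame with columns `total_n` and `fvfm`, n >= 3 and
#'   non-constant `total_n`.
#' @return An object of class `nitrogen_calibration` with fields `slope`,
#'   `intercept`, `r_squared`, `n` and the underlying `lm` fit.
#' @export
#' @examples
#' fit <- fit_nitrogen_calibration(simulate_nitrogen_pairs())
#' glance(fit)
fit_nitrogen_calibration <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("total_n", "fvfm") %in% names(pairs))) {
    abort("`pairs` needs columns `total_n` and `fvfm`.")
  }
  if (nrow(pairs) < 3) abort("need at least 3 pairs.")
  if (sd(pairs$total_n) == 0) {
    abort("total nitrogen values are constant: the fit is degenerate.",
          class = "fluoroscan_degenerate_fit")
  }
  fit <- lm(fvfm ~ total_n, data = pairs)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, n = nrow(pairs), fit = fit),
    class = "nitrogen_calibration"
  )
}

#' @export
print.nitrogen_calibration <- function(x, ...) {
  cat(sprintf(
    "<nitrogen_calibration> Fv/Fm = %.4f + %.5f * totalN, R^2 = %.3f, n = %d\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @export
predict.nitrogen_calibration <- function(object, total_n, ...) {
  object$intercept + object$slope * total_n
}

#' Estimate total nitrogen from an observed Fv/Fm
#'
#' Inverse of the linear calibration: `(fvfm - intercept) / slope`.
#' @param calibration A `nitrogen_calibration`.
#' @param fvfm Observed Fv/Fm value(s).
#' @return Total nitrogen estimate(s), mg N g^-1 dw.
#' @export
estimate_total_nitrogen <- function(calibration, fvfm) {
  if (!inherits(calibration, "nitrogen_calibration")) {
    abort("`calibration` must be a nitrogen_calibration.")
  }
  (fvfm - calibration$intercept) / calibration$slope
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy nitrogen_calibration
#' @export
tidy.nitrogen_calibration <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "total_n"),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @method glance nitrogen_calibration
#' @export
glance.nitrogen_calibration <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n = x$n,
                 sigma = summary(x$fit)$sigma)
}

# --- Nessler total-nitrogen assay -------------------------------------------

# mass fraction of N in ammonium sulfate, 2 * 14.007 / 132.14
N_FRACTION_AMMONIUM_SULFATE <- 2 * 14.007 / 132.14

#' Describe a Nessler total-nitrogen assay
#'
#' Bookkeeping for the spectrophotometric total-nitrogen determination: a
#' standard series of 0-10 mL of 10 mg/L ammonium sulfate read at 480 nm, a
#' sample absorbance, and the digestion bookkeeping (0.1 g dry sample
#' digested and diluted to 50 mL, 1 mL aliquot reacted).
#'
#' @param standard_od480 Absorbances of the standard series, one per volume.
#' @param sample_od480 Sample absorbance at 480 nm.
#' @param standard_volumes Standard volumes, mL (strictly increasing).
#' @param standard_conc_mg_l Concentration of the ammonium sulfate standard.
#' @param sample_mass_g Dry sample mass digested, g.
#' @param digest_volume_ml Final digest volume, mL.
#' @param aliquot_ml Reacted aliquot volume, mL.
#' @return An object of class `nessler_assay`.
#' @export
nessler_assay <- function(standard_od480, sample_od480,
                          standard_volumes = c(0, 2, 4, 6, 8, 10),
                          standard_conc_mg_l = 10,
                          sample_mass_g = 0.1, digest_volume_ml = 50,
                          aliquot_ml = 1) {
  if (length(standard_od480) != length(standard_volumes)) {
    abort("one OD per standard volume is required.")
  }
  if (any(diff(standard_volumes) <= 0)) {
    abort("standard volumes must be strictly increasing.")
  }
  if (any(standard_od480 < 0) || sample_od480 < 0) {
    abort("absorbances must be non-negative.")
  }
  structure(
    list(standard_volumes = standard_volumes,
         standard_od480 = standard_od480, sample_od480 = sample_od480,
         standard_conc_mg_l = standard_conc_mg_l,
         sample_mass_g = sample_mass_g,
         digest_volume_ml = digest_volume_ml, aliquot_ml = aliquot_ml),
    class = "nessler_assay"
  )
}

#' Total nitrogen from a Nessler assay
#'
#' Fits the least-squares standard curve of OD480 against the nitrogen mass
#' in each standard tube (standard volume x concentration x the N mass
#' fraction of ammonium sulfate, 28.014/132.14), inverts it at the sample
#' absorbance to get the N mass in the reacted aliquot, and scales by
#' `digest_volume / aliquot / sample_mass`.
#'
#' @param assay A [nessler_assay()].
#' @return Total nitrogen as mg N per g dry weight.
#' @export
#' @examples
#' od <- c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55)  # ideal linear standards
#' nessler_total_nitrogen(nessler_assay(od, sample_od480 = 0.25))
nessler_total_nitrogen <- function(assay) {
  if (!inherits(assay, "nessler_assay")) abort("`assay` must be a nessler_assay.")
  if (any(diff(assay$standard_od480) < 0)) {
    warn("standard absorbances are not monotone increasing; check the series.")
  }
  if (assay$sample_od480 > max(assay$standard_od480)) {
    abort("sample absorbance exceeds the top standard: dilute and re-read.",
          class = "fluoroscan_extrapolation")
  }
  # mg N per standard tube: mL * (mg/mL) * N mass fraction
  n_mg <- assay$standard_volumes * assay$standard_conc_mg_l / 1000 *
    N_FRACTION_AMMONIUM_SULFATE
  line <- lm(od ~ n, data = data.frame(od = assay$standard_od480, n = n_mg))
  slope <- unname(coef(line)[2])
  if (slope <= 0) abort("standard curve has non-positive slope.")
  n_aliquot_mg <- (assay$sample_od480 - unname(coef(line)[1])) / slope
  n_aliquot_mg <- max(n_aliquot_mg, 0)
  n_aliquot_mg * assay$digest_volume_ml / assay$aliquot_ml / assay$sample_mass_g
}
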