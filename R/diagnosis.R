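#' Normal ranges of the three physiology indicators
#'
#' Thresholds separating normal from stressed indicator levels for tomato
#' under the 200 umol actinic protocol: PhiPSII is normally around 0.40 and a
#' fall toward 0.30 signals stress; Fv/Fm is normally around 0.80 and a fall
#' below 0.75 means the PSII reaction centre is affected; the 550/510 ratio
#' normally sits above 1.5 and falls as chlorophyll synthesis is inhibited.
#' All are configurable.
#'
#' @param phipsii_normal,phipsii_stressed,fvfm_normal,fvfm_affected,ratio_normal_min
#'   Dimensionless thresholds; stressed/affected bounds must sit strictly
#'   below the normal levels.
#' @return An object of class `normal_ranges`.
#' @export
normal_ranges <- function(phipsii_normal = 0.40, phipsii_stressed = 0.30,
                          fvfm_normal = 0.80, fvfm_affected = 0.75,
                          ratio_normal_min = 1.5) {
  if (phipsii_stressed >= phipsii_normal || fvfm_affected >= fvfm_normal) {
    abort("stressed/affected bounds must sit strictly below the normal levels.")
  }
  if (ratio_normal_min <= 0) abort("`ratio_normal_min` must be positive.")
  structure(
    list(phipsii_normal = phipsii_normal, phipsii_stressed = phipsii_stressed,
         fvfm_normal = fvfm_normal, fvfm_affected = fvfm_affected,
         ratio_normal_min = ratio_normal_min),
    class = "normal_ranges"
  )
}

#' Classifier rule configuration
#'
#' Numeric cutoffs that turn the qualitative stress signatures into rules:
#' an indicator is "declining" when the least-squares slope of its day series
#' falls below `declining_slope`; a PhiPSII decline is "rapid" (disease-like)
#' when the steepest slope over any 3-consecutive-day window falls below
#' `rapid_slope`; canopy heterogeneity is flagged when the spatial standard
#' deviation of Fv/Fm exceeds `heterogeneity_std` (healthy canopies sit near
#' 0.01-0.03); lesions are flagged when the patchiness clumping score exceeds
#' `lesion_patchiness`. `impairment_threshold` defines lesion-grade tissue in
#' the Fv/Fm map for [patchiness_score()]: necrotic lesions fall to roughly
#' 30% of healthy Fv/Fm (about 0.24), well below this cutoff, while
#' physiological decline under nutrient stress stays above it.
#'
#' @param declining_slope,rapid_slope Per-day slope cutoffs (negative).
#' @param heterogeneity_std Fv/Fm spatial standard deviation cutoff.
#' @param lesion_patchiness Patchiness score cutoff in [0, 1].
#' @param impairment_threshold Fv/Fm level defining lesion-grade impairment.
#' @return An object of class `rule_cfg`.
#' @export
rule_cfg <- function(declining_slope = -0.01, rapid_slope = -0.05,
                     heterogeneity_std = 0.08, lesion_patchiness = 0.4,
                     impairment_threshold = 0.35) {
  structure(
    list(declining_slope = declining_slope, rapid_slope = rapid_slope,
         heterogeneity_std = heterogeneity_std,
         lesion_patchiness = lesion_patchiness,
         impairment_threshold = impairment_threshold),
    class = "rule_cfg"
  )
}

#' Flag a single day's indicator means against the normal ranges
#'
#' @param fvfm_mean,phipsii_mean,ratio_mean Plant-mean indicator values.
#' @param ranges A [normal_ranges()].
#' @return A one-row tibble of logical flags `phipsii_stressed`,
#'   `fvfm_affected`, `ratio_abnormal`.
#' @export
#' @examples
#' assess_snapshot(0.80, 0.29, 1.6)  # PhiPSII flag only
assess_snapshot <- function(fvfm_mean, phipsii_mean, ratio_mean,
                            ranges = normal_ranges()) {
  vals <- c(fvfm_mean, phipsii_mean, ratio_mean)
  if (any(!is.finite(vals))) abort("indicator means must be finite.")
  tibble::tibble(
    phipsii_stressed = phipsii_mean < ranges$phipsii_stressed,
    fvfm_affected = fvfm_mean < ranges$fvfm_affected,
    ratio_abnormal = ratio_mean < ranges$ratio_normal_min
  )
}

#' Spatial clumping score of impaired tissue
#'
#' Operationalises the observation that disease shows sudden, spatially
#' heterogeneous infection areas: let B be the set of defined plant pixels
#' whose value falls below `impairment_threshold`; the score is the mean,
#' over pixels of B that have at least one 4-neighbour inside the plant, of
#' the fraction of those plant neighbours that are also in B. Spatially
#' independent impairment at density p scores about p; compact lesions score
#' near 1. Returns 0 when B is empty.
#'
#' @param map An `indicator_map` (typically Fv/Fm).
#' @param impairment_threshold Values below this count as impaired.
#' @return A score in [0, 1].
#' @export
patchiness_score <- function(map, impairment_threshold = 0.35) {
  if (!inherits(map, "indicator_map")) abort("`map` must be an indicator_map.")
  defined <- is.finite(map$values)
  if (!any(defined)) abort("map has no defined pixels.")
  B <- defined & map$values < impairment_threshold
  if (!any(B)) return(0)
  h <- nrow(B); w <- ncol(B)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  nb_plant <- matrix(0L, h, w)
  nb_B <- matrix(0L, h, w)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb_plant <- nb_plant + shift(defined, d[1], d[2])
    nb_B <- nb_B + shift(B, d[1], d[2])
  }
  use <- B & nb_plant > 0
  if (!any(use)) return(0)
  mean(nb_B[use] / nb_plant[use])
}

traj_wide <- function(traj) {
  need <- c("day", "indicator", "mean", "std")
  miss <- setdiff(need, names(traj))
  if (length(miss) > 0) {
    abort(sprintf("trajectory is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  wide <- traj |>
    dplyr::select(dplyr::all_of(need)) |>
    tidyr::pivot_wider(names_from = "indicator",
                       values_from = c("mean", "std")) |>
    dplyr::arrange(.data$day)
  need_cols <- c("mean_fvfm", "mean_phipsii", "mean_r550_510", "std_fvfm")
  miss <- setdiff(need_cols, names(wide))
  if (length(miss) > 0 || anyNA(wide[need_cols])) {
    abort("all three indicators (fvfm, phipsii, r550_510) are required each day.")
  }
  if (any(diff(wide$day) <= 0)) abort("days must be strictly increasing.")
  wide
}

series_slope <- function(day, y) {
  if (length(day) < 2) return(0)
  unname(coef(lm(y ~ day))[2])
}

# Steepest least-squares slope over any window of 3 consecutive days.
steepest_window_slope <- function(day, y, width = 3L) {
  n <- length(day)
  if (n < width) return(series_slope(day, y))
  min(vapply(seq_len(n - width + 1L), function(i) {
    series_slope(day[i:(i + width - 1L)], y[i:(i + width - 1L)])
  }, numeric(1)))
}

label_prefix <- function(wide, patchiness, ranges, cfg) {
  n <- nrow(wide)
  last <- wide[n, ]
  flags <- assess_snapshot(last$mean_fvfm, last$mean_phipsii,
                           last$mean_r550_510, ranges)
  sl_phi <- series_slope(wide$day, wide$mean_phipsii)
  sl_fvfm <- series_slope(wide$day, wide$mean_fvfm)
  sl_ratio <- series_slope(wide$day, wide$mean_r550_510)
  rapid <- steepest_window_slope(wide$day, wide$mean_phipsii) < cfg$rapid_slope
  het <- max(wide$std_fvfm) > cfg$heterogeneity_std
  patchy <- length(patchiness) > 0 && max(patchiness) > cfg$lesion_patchiness
  declining <- sl_phi < cfg$declining_slope

  evidence <- tibble::tibble(
    phipsii_declining = declining,
    fvfm_below_affected = flags$fvfm_affected,
    ratio_below_normal = flags$ratio_abnormal,
    heterogeneity_rising = het,
    rapid_decline = rapid,
    patchy_lesions = patchy
  )

  label <-
    if (rapid || patchy) {
      "disease"
    } else if (declining && sl_fvfm < cfg$declining_slope &&
               sl_ratio < cfg$declining_slope && het && !patchy) {
      "nitrogen_deficiency"
    } else if (declining && flags$phipsii_stressed &&
               flags$fvfm_affected && flags$ratio_abnormal) {
      "drought_severe"
    } else if (declining && flags$phipsii_stressed &&
               !flags$fvfm_affected && !flags$ratio_abnormal) {
      "drought_early"
    } else if (!declining && !any(unlist(flags))) {
      "healthy"
    } else {
      "indeterminate"
    }
  list(label = label, evidence = evidence, flags = flags)
}

#' Classify the stress type from an indicator trajectory
#'
#' Applies the rule table distilled from the stress signatures:
#' \itemize{
#'   \item `drought_early`: PhiPSII declining and below its stressed bound
#'     while Fv/Fm and 550/510 are still normal (stomatal limitation precedes
#'     photoinhibition and chlorosis).
#'   \item `drought_severe`: a drought history in which Fv/Fm and 550/510
#'     have now also fallen below their bounds (late, wilted stage).
#'   \item `nitrogen_deficiency`: all three indicators declining gradually,
#'     with the spatial standard deviation of Fv/Fm rising above the
#'     heterogeneity cutoff (old leaves lead new ones) but no lesion-grade
#'     patchiness.
#'   \item `disease`: a rapid PhiPSII decline or lesion-grade patchiness;
#'     when both the disease and nitrogen-deficiency rules fire, disease wins
#'     (acting before an infection spreads matters more than a false alarm).
#'   \item `healthy`: no flags throughout; otherwise `indeterminate`.
#' }
#'
#' Every day-prefix of at least 3 days is labelled from its own cumulative
#' evidence; the diagnosis is the latest consistent (non-healthy,
#' non-indeterminate) label, so trailing recovered days never erase an
#' established severe diagnosis.
#'
#' @param traj Tidy trajectory tibble with columns `day`, `indicator`
#'   (`fvfm`, `phipsii`, `r550_510`), `mean`, `std` — one row per indicator
#'   per day, as produced by [summarize_maps()]. At least 3 days.
#' @param patchiness Optional numeric vector of per-day patchiness scores
#'   (from [patchiness_score()] on the Fv/Fm maps).
#' @param ranges A [normal_ranges()].
#' @param cfg A [rule_cfg()].
#' @param note Optional free-text exclusion note (e.g. recorded temperature)
#'   carried into the report.
#' @return An object of class `stress_diagnosis`: `label`, `confidence`,
#'   per-day `evidence` tibble, `per_day_labels`, thresholds used.
#' @export
classify_stress <- function(traj, patchiness = NULL,
                            ranges = normal_ranges(), cfg = rule_cfg(),
                            note = NULL) {
  wide <- traj_wide(traj)
  n <- nrow(wide)
  if (n < 3) {
    abort("at least 3 days of data are required for classification.",
          class = "fluoroscan_insufficient_data")
  }
  if (!is.null(patchiness) && length(patchiness) != n) {
    abort("`patchiness` must have one score per day.")
  }
  res <- purrr::map(3:n, function(d) {
    label_prefix(wide[seq_len(d), ], patchiness[seq_len(d)], ranges, cfg)
  })
  labels <- vapply(res, `[[`, character(1), "label")
  informative <- labels[!labels %in% c("healthy", "indeterminate")]
  final <- if (length(informative) > 0) {
    informative[length(informative)]
  } else if (all(labels == "healthy")) "healthy" else "indeterminate"

  last_ev <- res[[length(res)]]$evidence
  support <- switch(final,
    healthy = mean(!unlist(last_ev)),
    drought_early = mean(c(last_ev$phipsii_declining,
                           !last_ev$fvfm_below_affected,
                           !last_ev$ratio_below_normal)),
    drought_severe = mean(c(last_ev$phipsii_declining,
                            last_ev$fvfm_below_affected,
                            last_ev$ratio_below_normal)),
    nitrogen_deficiency = mean(c(last_ev$phipsii_declining,
                                 last_ev$heterogeneity_rising,
                                 !last_ev$patchy_lesions)),
    disease = mean(c(last_ev$rapid_decline, last_ev$patchy_lesions)),
    indeterminate = 0
  )
  evidence <- dplyr::bind_cols(
    tibble::tibble(day = wide$day[3:n], label = labels),
    dplyr::bind_rows(purrr::map(res, "evidence"))
  )
  structure(
    list(label = final, confidence = support, evidence = evidence,
         per_day_labels = labels, ranges = ranges, cfg = cfg,
         note = note),
    class = "stress_diagnosis"
  )
}

#' @export
print.stress_diagnosis <- function(x, ...) {
  cat(sprintf("<stress_diagnosis> %s (confidence %.2f)\n", x$label,
              x$confidence))
  cat(sprintf("  per-day labels: %s\n", paste(x$per_day_labels, collapse = " -> ")))
  if (!is.null(x$note)) cat(sprintf("  note: %s\n", x$note))
  invisible(x)
}

#' Serialise a diagnosis report to JSON
#'
#' @param diagnosis A `stress_diagnosis`.
#' @param path Destination JSON path.
#' @export
write_diagnosis <- function(diagnosis, path) {
  if (!inherits(diagnosis, "stress_diagnosis")) {
    abort("`diagnosis` must be a stress_diagnosis.")
  }
  jsonlite::write_json(
    list(label = diagnosis$label, confidence = diagnosis$confidence,
         per_day_labels = diagnosis$per_day_labels,
         evidence = diagnosis$evidence,
         thresholds = c(unclass(diagnosis$ranges), unclass(diagnosis$cfg)),
         note = diagnosis$note),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
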