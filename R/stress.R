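#' Describe a stress time course
#'
#' A stress model couples a stress type to a per-day severity trajectory in
#' [0, 1] and a spatial mode. The spatial mode is fixed by physiology: drought
#' acts uniformly over the canopy (stomatal closure), nitrogen deficiency hits
#' old leaves first (nitrogen is remobilised out of them), and Botrytis-type
#' disease carves growing necrotic lesion patches.
#'
#' Default severity trajectories are day-indexed on the 9-day reference
#' experiment; monitoring fewer days observes a prefix of the same course
#' (truncated, never compressed), and longer windows hold the day-9 level:
#' \itemize{
#'   \item `none`: all zero.
#'   \item `drought`: a saturating ramp shaped so the generated canopy-mean
#'     PhiPSII traces the observed course -- about 0.4 on day 1, about 0.3 by
#'     day 5, flat near 0.25 over days 7-9 once leaves have wilted.
#'   \item `nitrogen_deficiency`: linear, reaching full severity on day 9; a
#'     gradual chronic stress.
#'   \item `disease`: reaches full severity by day 5; infection develops much
#'     faster than nutrient stress.
#' }
#'
#' @param stress_type One of `"none"`, `"drought"`, `"nitrogen_deficiency"`,
#'   `"disease"`.
#' @param n_days Length of the monitored time course (day indices 1..n_days).
#' @param severity_trajectory Optional numeric vector of per-day severities in
#'   [0, 1]; must be non-decreasing. Defaults per stress type as above.
#' @param lesion_growth_rate Lesion radius growth in pixels per day of active
#'   infection (disease only). `NULL` (default) scales the rate to the mean
#'   plant size in view, so lesions engulf most of a plant after 4 days of
#'   unchecked growth at any scene resolution.
#' @param lesions_per_plant Number of seeded infection sites per plant.
#' @param lesion_seed Seed controlling lesion placement, so a model applied to
#'   the same field is reproducible day to day.
#' @param old_leaf_lead_days Nitrogen deficiency only: new leaves lag the
#'   trajectory by this many days, so old leaves reach any given severity
#'   this many days before new leaves.
#' @return An object of class `stress_model`.
#' @export
#' @examples
#' stress_model("drought")
stress_model <- function(stress_type = c("none", "drought",
                                         "nitrogen_deficiency", "disease"),
                         n_days = 9L,
                         severity_trajectory = NULL,
                         lesion_growth_rate = NULL,
                         lesions_per_plant = 2L,
                         lesion_seed = 1L,
                         old_leaf_lead_days = 2L) {
  stress_type <- match.arg(stress_type)
  n_days <- as.integer(n_days)
  if (n_days < 1) abort("`n_days` must be at least 1.")
  if (is.null(severity_trajectory)) {
    severity_trajectory <- default_severity(stress_type, n_days)
  }
  if (length(severity_trajectory) != n_days) {
    abort("`severity_trajectory` must have one entry per day.")
  }
  if (any(severity_trajectory < 0 | severity_trajectory > 1)) {
    abort("severities must lie in [0, 1].")
  }
  if (any(diff(severity_trajectory) < -1e-12)) {
    abort("`severity_trajectory` must be non-decreasing.")
  }
  spatial_mode <- switch(stress_type,
    none = "uniform",
    drought = "uniform",
    nitrogen_deficiency = "old_leaves_first",
    disease = "patchy_lesions"
  )
  structure(
    list(stress_type = stress_type,
         n_days = n_days,
         severity_trajectory = severity_trajectory,
         spatial_mode = spatial_mode,
         lesion_growth_rate = lesion_growth_rate,
         lesions_per_plant = as.integer(lesions_per_plant),
         lesion_seed = as.integer(lesion_seed),
         old_leaf_lead_days = as.integer(old_leaf_lead_days)),
    class = "stress_model"
  )
}

# Default severities are day-indexed on the 9-day reference experiment;
# a shorter monitored window is a prefix of that course (truncated, never
# compressed), and longer windows stay at the day-9 level.
default_severity <- function(stress_type, n_days) {
  d <- seq_len(n_days)
  switch(stress_type,
    none = rep(0, n_days),
    drought = {
      # shape anchored to the reported PhiPSII course (0.4 -> ~0.3 by day 5,
      # plateau ~0.25 from day 7) through phi_op(s) = 0.40 - 0.15 s
      shape <- c(0, 0.15, 0.30, 0.50, 0.70, 0.85, 1, 1, 1)
      shape[pmin(d, 9L)]
    },
    nitrogen_deficiency = pmin(1, (d - 1) / 8),
    disease = pmin(1, (d - 1) / 4)
  )
}

#' @export
print.stress_model <- function(x, ...) {
  cat(sprintf("<stress_model> %s (%s), %d day(s), severity %.2f -> %.2f\n",
              x$stress_type, x$spatial_mode, x$n_days,
              x$severity_trajectory[1],
              x$severity_trajectory[x$n_days]))
  invisible(x)
}

# Deterministic lesion centres: sampled plant pixels, lesions_per_plant per
# connected plant, driven by lesion_seed only.
lesion_centres <- function(field, model) {
  labels <- EBImage::bwlabel(field$footprint * 1)
  n_comp <- max(labels)
  set.seed(model$lesion_seed)
  out <- list()
  for (comp in seq_len(n_comp)) {
    px <- which(labels == comp)
    k <- min(model$lesions_per_plant, length(px))
    out[[comp]] <- sample(px, k)
  }
  idx <- unlist(out)
  h <- nrow(field$footprint)
  cbind(row = (idx - 1L) %% h + 1L, col = (idx - 1L) %/% h + 1L)
}

#' Apply a stress model to a physiology field at a given day
#'
#' Returns a modified copy of the field with the day's severity imposed.
#' Drought lowers PhiPSII first (stomatal limitation); Fv/Fm and greenness are
#' touched only beyond a severe-drought threshold (severity > 0.7), matching
#' the observation that Fv/Fm and 550/510 decline only in the late, wilted
#' stage. Nitrogen deficiency lowers all three indicators gradually with old
#' leaves leading new leaves by `old_leaf_lead_days`, which drives up the
#' spatial standard deviation of Fv/Fm. Disease carves circular lesions whose
#' radius grows with severity; inside a lesion all three quantities drop to
#' 30% of their healthy values.
#'
#' @param field A [build_scene()] result (healthy baseline).
#' @param model A [stress_model()].
#' @param day Day index within `1..model$n_days`.
#' @return A new `physiology_field`.
#' @export
#' @examples
#' f <- build_scene(scene_spec(image_height = 120, image_width = 160,
#'                             n_plants = 1), seed = 1)
#' d5 <- apply_stress(f, stress_model("drought"), day = 5)
#' mean(d5$phi_op[d5$footprint])
apply_stress <- function(field, model, day) {
  validate_physiology_field(field)
  if (!inherits(model, "stress_model")) abort("`model` must be a stress_model.")
  day <- as.integer(day)
  if (day < 1 || day > model$n_days) {
    abort(sprintf("`day` must be within 1..%d.", model$n_days))
  }
  if (model$stress_type == "none") return(field)
  s <- model$severity_trajectory[day]
  out <- field
  fp <- field$footprint

  if (model$stress_type == "drought") {
    excess <- max(0, s - 0.7) / 0.3   # severe-drought fraction
    out$phi_op[fp] <- pmax(field$phi_op[fp] - 0.15 * s, 0.01)
    out$phi_max[fp] <- field$phi_max[fp] - 0.08 * excess
    out$chroma[fp] <- field$chroma[fp] - ratio_to_chroma(0.20) * excess
  } else if (model$stress_type == "nitrogen_deficiency") {
    traj <- model$severity_trajectory
    s_old <- s
    s_new <- traj[max(day - model$old_leaf_lead_days, 1L)]
    old_px <- fp & field$age == 1L
    new_px <- fp & field$age == 2L
    out$phi_max[old_px] <- field$phi_max[old_px] - 0.35 * s_old
    out$phi_max[new_px] <- field$phi_max[new_px] - 0.15 * s_new
    out$phi_op[old_px] <- field$phi_op[old_px] - 0.25 * s_old
    out$phi_op[new_px] <- field$phi_op[new_px] - 0.12 * s_new
    out$chroma[old_px] <- field$chroma[old_px] - ratio_to_chroma(0.60) * s_old
    out$chroma[new_px] <- field$chroma[new_px] - ratio_to_chroma(0.30) * s_new
  } else if (model$stress_type == "disease") {
    if (s > 0) {
      centres <- lesion_centres(field, model)
      growth <- model$lesion_growth_rate
      if (is.null(growth)) {
        # auto: scale to the plants in view so lesions cover most of a plant
        # after 4 days of unchecked growth, whatever the scene resolution
        n_comp <- max(EBImage::bwlabel(fp * 1))
        growth <- 0.16 * sqrt(sum(fp) / n_comp / pi)
      }
      # severity 1 corresponds to 4 days of unchecked lesion growth
      radius <- growth * 4 * s
      h <- nrow(fp); w <- ncol(fp)
      lesion <- matrix(FALSE, h, w)
      for (i in seq_len(nrow(centres))) {
        px <- ellipse_pixels(h, w, centres[i, "row"], centres[i, "col"],
                             radius, radius, 0)
        lesion[px] <- TRUE
      }
      lesion <- lesion & fp
      out$phi_max[lesion] <- 0.3 * field$phi_max[lesion]
      out$phi_op[lesion] <- 0.3 * field$phi_op[lesion]
      out$chroma[lesion] <- 0.3 * field$chroma[lesion]
    }
  } else {
    abort(sprintf("unknown stress_type '%s'.", model$stress_type))
  }
  out$phi_op[fp] <- pmin(out$phi_op[fp], out$phi_max[fp])
  validate_physiology_field(out)
}
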