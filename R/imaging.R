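#' Describe the imaging model (optics, sensor, protocol)
#'
#' Captures how the instrument turns a physiology field into camera counts:
#' the fluorescence gain, radial optical vignetting, additive Gaussian read
#' noise, optional signal-proportional shot noise, and the 12-bit ADC. Light
#' levels of the measurement protocol are carried as metadata only (measuring
#' 0.1, actinic 200, saturating > 6000 umol photons m^-2 s^-1).
#'
#' @param fm_gain Counts of Fm per unit chroma at the optical centre.
#' @param vignetting_strength Relative fall-off at the image corner; the
#'   vignetting multiplier is `1 - strength * (r/rmax)^2`, always in (0, 1].
#' @param read_noise_sd Additive Gaussian read noise, counts.
#' @param shot_noise If `TRUE`, adds Gaussian noise with variance equal to the
#'   signal (Poisson-like photon noise).
#' @param bit_depth ADC bit depth; counts are clipped to `[0, 2^bit_depth - 1]`.
#' @param quantize `NULL` (default) rounds counts to integers whenever any
#'   noise source is enabled; set `FALSE` to keep continuous counts (used for
#'   algebraic round-trip checks) or `TRUE` to force rounding.
#' @param r510_gain Counts of the 510 nm reflectance frame on plant tissue at
#'   the optical centre.
#' @param background_reflectance Counts (R510, R550) of the soil/tray
#'   background before vignetting; soil has a 550/510 ratio below 1.
#' @param light_levels Protocol light levels, metadata only.
#' @return An object of class `imaging_model`.
#' @export
imaging_model <- function(fm_gain = 3000,
                          vignetting_strength = 0.15,
                          read_noise_sd = 5,
                          shot_noise = TRUE,
                          bit_depth = 12L,
                          quantize = NULL,
                          r510_gain = 500,
                          background_reflectance = c(R510 = 320, R550 = 280),
                          light_levels = c(measuring = 0.1, actinic = 200,
                                           saturating = 6000)) {
  if (vignetting_strength < 0 || vignetting_strength >= 1) {
    abort("`vignetting_strength` must lie in [0, 1).")
  }
  if (read_noise_sd < 0) abort("`read_noise_sd` must be >= 0.")
  structure(
    list(fm_gain = fm_gain, vignetting_strength = vignetting_strength,
         read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
         bit_depth = as.integer(bit_depth), quantize = quantize,
         r510_gain = r510_gain, background_reflectance = background_reflectance,
         light_levels = light_levels),
    class = "imaging_model"
  )
}

#' A noise-free imaging model
#'
#' Convenience preset: no read noise, no shot noise, no quantisation. With it,
#' indicator maps computed from a rendered stack recover the generating
#' physiology field to floating-point round-off.
#' @inheritParams imaging_model
#' @param ... Passed to [imaging_model()].
#' @export
imaging_model_noiseless <- function(...) {
  imaging_model(read_noise_sd = 0, shot_noise = FALSE, quantize = FALSE, ...)
}

#' Render a physiology field into an acquisition stack
#'
#' Inverts the indicator definitions: per plant pixel, `Fm = fm_gain * chroma *
#' vignetting`, `Fo = Fm * (1 - Fv/Fm)`, `Fm' = Fm * (1 - q)` with the
#' quenching factor `q = 0.6 * (Fv/Fm - PhiPSII)` (so light-adapted quenching
#' grows as the operating efficiency falls below the maximum), and `F = Fm' *
#' (1 - PhiPSII)`. In the noiseless case the stack therefore inverts exactly
#' to the field's Fv/Fm and PhiPSII, and `Fo <= Fm`, `F <= Fm' <= Fm` hold by
#' construction. Reflectance frames are built so R550/R510 equals the
#' chroma-mapped 550/510 target on plant pixels. Background pixels carry only
#' the scene's background level (plus noise) in the fluorescence frames.
#'
#' A warning is raised when more than 0.1% of footprint pixels saturate the
#' ADC.
#'
#' @param field A `physiology_field`.
#' @param imaging An [imaging_model()].
#' @param seed Seed for the noise draws.
#' @param day,position Metadata for the resulting stack.
#' @return A [frame_stack()].
#' @export
#' @examples
#' f <- build_scene(scene_spec(image_height = 80, image_width = 100,
#'                             n_plants = 1), seed = 1)
#' stk <- render_stack(f, imaging_model_noiseless(), seed = 1)
#' range(stk$frames$Fm)
render_stack <- function(field, imaging = imaging_model(), seed = 1L,
                         day = 1L, position = c(0L, 0L)) {
  validate_physiology_field(field)
  if (!inherits(imaging, "imaging_model")) abort("`imaging` must be an imaging_model.")
  if (any(field$phi_max < 0 | field$phi_max >= 1) ||
      any(field$phi_op < 0 | field$phi_op >= 1)) {
    abort("phi values must lie in [0, 1).")
  }
  fp <- field$footprint
  h <- nrow(fp); w <- ncol(fp)
  v <- vignetting_field(h, w, imaging$vignetting_strength)
  bg <- field$spec$background_level

  Fm <- matrix(bg, h, w)
  Fm[fp] <- imaging$fm_gain * field$chroma[fp] * v[fp]
  Fo <- matrix(bg, h, w)
  Fo[fp] <- Fm[fp] * (1 - field$phi_max[fp])
  q <- 0.6 * (field$phi_max - field$phi_op)
  Fmp <- matrix(bg, h, w)
  Fmp[fp] <- Fm[fp] * (1 - q[fp])
  Ff <- matrix(bg, h, w)
  Ff[fp] <- Fmp[fp] * (1 - field$phi_op[fp])

  R510 <- imaging$background_reflectance[["R510"]] * v
  R550 <- imaging$background_reflectance[["R550"]] * v
  R510[fp] <- imaging$r510_gain * v[fp]
  R550[fp] <- R510[fp] * chroma_to_ratio(field$chroma[fp])

  frames <- list(Fo = Fo, Fm = Fm, F = Ff, Fm_prime = Fmp,
                 R510 = R510, R550 = R550)

  noisy <- imaging$read_noise_sd > 0 || imaging$shot_noise
  quantize <- imaging$quantize %||% noisy
  cap <- 2^imaging$bit_depth - 1
  set.seed(seed)
  n_sat <- 0L
  frames <- lapply(frames, function(f) {
    if (imaging$read_noise_sd > 0) {
      f <- f + rnorm(length(f), 0, imaging$read_noise_sd)
    }
    if (imaging$shot_noise) {
      f <- f + rnorm(length(f), 0, sqrt(pmax(f, 0)))
    }
    n_sat <<- n_sat + sum(f[fp] > cap)
    f <- pmin(pmax(f, 0), cap)
    if (quantize) f <- round(f)
    f
  })
  if (sum(fp) > 0 && n_sat > 0.001 * length(FRAME_ORDER) * sum(fp)) {
    warn(sprintf("%d footprint samples saturated the %d-bit ADC (> 0.1%%).",
                 n_sat, imaging$bit_depth))
  }
  frame_stack(frames, stack_metadata(position = position, day = day,
                                     light_levels = imaging$light_levels,
                                     bit_depth = imaging$bit_depth))
}

#' Generate a multi-day ground-truthed dataset
#'
#' Runs the stress model over a day series, renders one acquisition stack per
#' day, and (optionally) writes stacks plus ground-truth sidecars to disk.
#' Ground truth per day is the stressed physiology field (footprint and
#' per-pixel phi fields), stored as a compressed `.rds` array container with a
#' `manifest.json` listing all files; stacks go through [write_stack()].
#'
#' @param spec A [scene_spec()].
#' @param model A [stress_model()].
#' @param imaging An [imaging_model()].
#' @param days Integer vector of day indices (non-empty, within the model's
#'   day range).
#' @param seed Master seed; per-day noise seeds are derived as `seed + day`.
#' @param out_dir Optional output directory; created if needed.
#' @return A list with elements `stacks` (list of `frame_stack`), `truth`
#'   (list of `physiology_field`), `days`, and `paths` (when written).
#' @export
generate_dataset <- function(spec, model, imaging = imaging_model(),
                             days = seq_len(model$n_days), seed = 42L,
                             out_dir = NULL) {
  if (length(days) == 0L) abort("`days` must be non-empty.")
  base <- build_scene(spec, seed = seed)
  truth <- lapply(days, function(d) apply_stress(base, model, d))
  stacks <- lapply(seq_along(days), function(i) {
    render_stack(truth[[i]], imaging, seed = seed + days[i], day = days[i])
  })
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- lapply(seq_along(days), function(i) {
      stem <- file.path(out_dir, sprintf("day%02d", days[i]))
      write_stack(stacks[[i]], paste0(stem, ".tif"))
      saveRDS(list(footprint = truth[[i]]$footprint,
                   phi_max = truth[[i]]$phi_max,
                   phi_op = truth[[i]]$phi_op,
                   chroma = truth[[i]]$chroma,
                   age = truth[[i]]$age),
              paste0(stem, "_truth.rds"))
      c(stack = basename(paste0(stem, ".tif")),
        truth = basename(paste0(stem, "_truth.rds")))
    })
    jsonlite::write_json(
      list(stress_type = model$stress_type, days = days, seed = seed,
           severity = model$severity_trajectory[days],
           files = lapply(paths, as.list)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
    )
  }
  list(stacks = stacks, truth = truth, days = days, paths = paths)
}
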