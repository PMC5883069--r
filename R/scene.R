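#' Specify a synthetic seedling-bed scene
#'
#' A scene specification describes one camera field of view on the seedling
#' bed: image geometry, how many plants are in view, their leaf count, and the
#' dark-background intensity of the fluorescence frames. The default geometry
#' (520 x 696 pixels) matches the acquisition resolution of the monitoring
#' instrument the generator emulates.
#'
#' @param image_height,image_width Image dimensions in pixels.
#' @param n_plants Number of plants in the field of view (>= 1).
#' @param leaves_per_plant Leaves per plant; the first half (rounded up) are
#'   tagged as old (lower, outer) leaves, the rest as new leaves. Leaf age
#'   matters under nitrogen deficiency, where old leaves respond first.
#' @param background_level Mean background intensity (counts) of the
#'   fluorescence frames; the non-plant area does not fluoresce, so this is
#'   dark current plus stray light.
#' @param rng_seed Default seed used by [build_scene()] when none is given.
#'
#' @return An object of class `scene_spec`.
#' @export
#' @examples
#' scene_spec(n_plants = 2)
scene_spec <- function(image_height = 520L,
                       image_width = 696L,
                       n_plants = 4L,
                       leaves_per_plant = 6L,
                       background_level = 30,
                       rng_seed = 1L) {
  stopifnot_scalar_number(image_height, "image_height", positive = TRUE)
  stopifnot_scalar_number(image_width, "image_width", positive = TRUE)
  stopifnot_scalar_number(n_plants, "n_plants")
  stopifnot_scalar_number(leaves_per_plant, "leaves_per_plant")
  stopifnot_scalar_number(background_level, "background_level")
  if (n_plants < 1) abort("`n_plants` must be at least 1.", class = "fluoroscan_invalid_spec")
  if (leaves_per_plant < 1) {
    abort("`leaves_per_plant` must be at least 1 (zero-area plants are not a scene).",
          class = "fluoroscan_invalid_spec")
  }
  structure(
    list(
      image_height = as.integer(image_height),
      image_width = as.integer(image_width),
      n_plants = as.integer(n_plants),
      leaves_per_plant = as.integer(leaves_per_plant),
      leaf_age_classes = c("old", "new"),
      background_level = background_level,
      rng_seed = as.integer(rng_seed)
    ),
    class = "scene_spec"
  )
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %d x %d px, %d plant(s) x %d leaves, background %.0f counts\n",
    x$image_height, x$image_width, x$n_plants, x$leaves_per_plant,
    x$background_level
  ))
  invisible(x)
}

# Plant centres laid out on a grid with margins so plants never touch.
plant_centres <- function(spec) {
  n <- spec$n_plants
  ncg <- ceiling(sqrt(n))
  nrg <- ceiling(n / ncg)
  ys <- spec$image_height * (seq_len(nrg) - 0.5) / nrg
  xs <- spec$image_width * (seq_len(ncg) - 0.5) / ncg
  grid <- expand.grid(y = ys, x = xs)
  grid[seq_len(n), , drop = FALSE]
}

# Paint one rotated ellipse (a leaf) into integer matrices, restricted to a
# bounding box for speed. Returns the linear indices of covered pixels.
ellipse_pixels <- function(h, w, cy, cx, a, b, theta) {
  r <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  if (length(rows) == 0L || length(cols) == 0L) return(integer(0))
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  # coordinates in the leaf frame: u along the leaf axis, v across it
  u <- outer(dy, dx, function(y, x) y * st + x * ct)
  v <- outer(dy, dx, function(y, x) -y * ct + x * st)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(integer(0))
  (cols[idx[, 2]] - 1L) * h + rows[idx[, 1]]
}

#' Build a ground-truth physiology field for a synthetic scene
#'
#' Generates the per-pixel "true" physiology that the imaging model will later
#' render into camera frames. Each plant is a rosette of elliptical leaves
#' radiating from its centre; the outer (first) leaves are tagged old, the
#' inner ones new. Healthy tissue carries the preset values Fv/Fm = 0.80,
#' PhiPSII = 0.40 (under 200 umol actinic light) and a greenness driver
#' (chroma) giving a 550/510 reflectance ratio of 1.6 -- all inside the normal
#' ranges for unstressed tomato. Off the plant footprint all fields are zero.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed; generation is bit-reproducible for a given
#'   (spec, seed).
#' @return An object of class `physiology_field`: matrices `phi_max` (Fv/Fm),
#'   `phi_op` (PhiPSII), `chroma`, logical `footprint`, integer `age`
#'   (0 background, 1 old leaf, 2 new leaf), plus the generating `spec`.
#' @export
#' @examples
#' field <- build_scene(scene_spec(n_plants = 2), seed = 1)
#' mean(field$phi_max[field$footprint])
build_scene <- function(spec, seed = spec$rng_seed) {
  if (!inherits(spec, "scene_spec")) abort("`spec` must be a scene_spec.")
  set.seed(seed)
  h <- spec$image_height
  w <- spec$image_width
  footprint <- matrix(FALSE, h, w)
  age <- matrix(0L, h, w)

  centres <- plant_centres(spec)
  # leaf size scales with plant spacing so neighbouring plants stay disjoint
  pitch <- min(spec$image_height / ceiling(spec$n_plants / ceiling(sqrt(spec$n_plants))),
               spec$image_width / ceiling(sqrt(spec$n_plants)))
  a0 <- 0.22 * pitch   # semi-major axis of an old leaf
  b0 <- 0.45 * a0
  if (a0 < 1 || b0 < 1) {
    abort("Scene too crowded: leaves would have zero area.",
          class = "fluoroscan_invalid_spec")
  }

  L <- spec$leaves_per_plant
  n_old <- ceiling(L / 2)
  for (p in seq_len(spec$n_plants)) {
    rot <- runif(1, 0, 2 * pi)
    for (k in seq_len(L)) {
      is_old <- k <= n_old
      theta <- rot + 2 * pi * (k - 1) / L + rnorm(1, 0, 0.06)
      scale_k <- if (is_old) 1 else 0.62
      a <- a0 * scale_k * runif(1, 0.92, 1.08)
      b <- b0 * scale_k * runif(1, 0.92, 1.08)
      d <- 0.85 * a   # leaf base near the plant centre keeps the rosette connected
      cy <- centres$y[p] + d * sin(theta)
      cx <- centres$x[p] + d * cos(theta)
      px <- ellipse_pixels(h, w, cy, cx, a, b, theta)
      footprint[px] <- TRUE
      age[px] <- if (is_old) 1L else 2L
    }
  }
  if (!any(footprint)) {
    abort("Generated scene has an empty plant footprint.",
          class = "fluoroscan_invalid_spec")
  }

  phi_max <- matrix(0, h, w)
  phi_op <- matrix(0, h, w)
  chroma <- matrix(0, h, w)
  phi_max[footprint] <- 0.80
  phi_op[footprint] <- 0.40
  chroma[footprint] <- ratio_to_chroma(1.6)

  structure(
    list(phi_max = phi_max, phi_op = phi_op, chroma = chroma,
         footprint = footprint, age = age, spec = spec, seed = as.integer(seed)),
    class = "physiology_field"
  )
}

#' @export
print.physiology_field <- function(x, ...) {
  n_fp <- sum(x$footprint)
  cat(sprintf(
    "<physiology_field> %d x %d px, %d plant pixels (%.1f%%)\n",
    nrow(x$footprint), ncol(x$footprint), n_fp,
    100 * n_fp / length(x$footprint)
  ))
  if (n_fp > 0) {
    cat(sprintf("  footprint means: Fv/Fm %.3f, PhiPSII %.3f, 550/510 %.3f\n",
                mean(x$phi_max[x$footprint]), mean(x$phi_op[x$footprint]),
                mean(chroma_to_ratio(x$chroma[x$footprint]))))
  }
  invisible(x)
}

validate_physiology_field <- function(field) {
  if (!inherits(field, "physiology_field")) abort("expected a physiology_field.")
  fp <- field$footprint
  ok <- all(field$phi_op[fp] >= 0) &&
    all(field$phi_op[fp] <= field$phi_max[fp] + 1e-12) &&
    all(field$phi_max[fp] < 1)
  if (!ok) abort("physiology_field violates 0 <= phi_op <= phi_max < 1 on the footprint.")
  if (any(field$phi_max[!fp] != 0) || any(field$phi_op[!fp] != 0) ||
      any(field$chroma[!fp] != 0)) {
    abort("physiology_field must be zero off the footprint.")
  }
  invisible(field)
}
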