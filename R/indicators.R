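INDICATOR_SCALES <- list(
  fvfm = c(0, 0.85),
  phipsii = c(0, 0.85),
  r550_510 = c(0, 2.0)
)

new_indicator_map <- function(values, indicator, mask, n_clamped, n_dim_denominator) {
  structure(
    list(values = values, indicator = indicator, mask = mask,
         n_clamped = n_clamped, n_dim_denominator = n_dim_denominator),
    class = "indicator_map"
  )
}

#' @export
print.indicator_map <- function(x, ...) {
  nd <- sum(is.finite(x$values))
  cat(sprintf("<indicator_map> %s, %d x %d px, %d defined pixels",
              x$indicator, nrow(x$values), ncol(x$values), nd))
  if (nd > 0) cat(sprintf(", mean %.3f", mean(x$values[is.finite(x$values)])))
  cat("\n")
  if (x$n_clamped > 0) {
    cat(sprintf("  %d negative value(s) clamped to 0\n", x$n_clamped))
  }
  invisible(x)
}

# Shared ratio-of-frames machinery for all three indicators. Undefined pixels
# (off-mask, or denominator below eps = 1% of the denominator's robust
# maximum) carry NA; noise-induced negatives are clamped to 0 and counted so
# masks and maps stay pixel-aligned.
indicator_ratio_map <- function(numerator, denominator, mask, indicator,
                                clamp_negative = TRUE) {
  m <- if (inherits(mask, "plant_mask")) mask$mask else mask
  if (!matrix_dims_equal(numerator, denominator, m)) {
    abort("frames and mask must be co-registered (same shape).")
  }
  eps <- 0.01 * as.numeric(quantile(denominator, 0.99))
  defined <- m & denominator >= pmax(eps, .Machine$double.eps)
  values <- matrix(NA_real_, nrow(numerator), ncol(numerator))
  values[defined] <- numerator[defined] / denominator[defined]
  n_clamped <- 0L
  if (clamp_negative) {
    neg <- defined & !is.na(values) & values < 0
    n_clamped <- sum(neg)
    values[neg] <- 0
  }
  new_indicator_map(values, indicator, mask, n_clamped,
                    n_dim_denominator = sum(m & !defined))
}

#' Maximum PSII quantum efficiency map, Fv/Fm = (Fm - Fo) / Fm
#'
#' Computed per plant pixel from the dark-adapted minimal (Fo) and maximal
#' (Fm) fluorescence frames. Pixels off the mask or with Fm below 1% of the
#' frame's robust maximum are marked undefined (NA); noise-induced negative
#' values are clamped to 0 and counted in the map's `n_clamped` field.
#' Healthy leaves sit near 0.8; values below 0.75 indicate an affected PSII
#' reaction centre.
#'
#' @param fo_frame,fm_frame Fluorescence frames, counts.
#' @param mask A [plant_mask()] or logical matrix co-registered with the
#'   frames.
#' @return An `indicator_map` with `indicator = "fvfm"`.
#' @export
#' @examples
#' m <- matrix(TRUE, 1, 1)
#' compute_fvfm(matrix(600, 1, 1), matrix(3000, 1, 1), m)$values
compute_fvfm <- function(fo_frame, fm_frame, mask) {
  m <- if (inherits(mask, "plant_mask")) mask$mask else mask
  if (!matrix_dims_equal(fo_frame, fm_frame, m)) {
    abort("frames and mask must be co-registered (same shape).")
  }
  indicator_ratio_map(fm_frame - fo_frame, fm_frame, mask, "fvfm")
}

#' Operating PSII quantum efficiency map, PhiPSII = (Fm' - F) / Fm'
#'
#' Computed per plant pixel from the steady-state (F) and light-adapted
#' maximal (Fm') fluorescence frames under actinic light. Under the 200 umol
#' protocol healthy leaves sit near 0.4; values falling toward 0.3 indicate
#' stress. Degenerate handling as in [compute_fvfm()].
#'
#' @param f_frame,fmp_frame Fluorescence frames, counts.
#' @inheritParams compute_fvfm
#' @return An `indicator_map` with `indicator = "phipsii"`.
#' @export
compute_phipsii <- function(f_frame, fmp_frame, mask) {
  m <- if (inherits(mask, "plant_mask")) mask$mask else mask
  if (!matrix_dims_equal(f_frame, fmp_frame, m)) {
    abort("frames and mask must be co-registered (same shape).")
  }
  indicator_ratio_map(fmp_frame - f_frame, fmp_frame, mask, "phipsii")
}

#' Relative reflectance ratio map, 550/510
#'
#' Per plant pixel, the 550 nm reflectance divided by the 510 nm reflectance:
#' a calibration-board-free greenness proxy that rises with chlorophyll
#' accumulation. Healthy canopies sit above 1.5. Pixels with a dim 510 nm
#' denominator are undefined.
#'
#' @param r550_frame,r510_frame Reflectance frames, counts.
#' @inheritParams compute_fvfm
#' @return An `indicator_map` with `indicator = "r550_510"`.
#' @export
compute_ratio_550_510 <- function(r550_frame, r510_frame, mask) {
  indicator_ratio_map(r550_frame, r510_frame, mask, "r550_510",
                      clamp_negative = FALSE)
}

#' Compute all three indicator maps from a stack
#'
#' @param stack A [frame_stack()].
#' @param mask A [plant_mask()].
#' @return Named list of `indicator_map`s (`fvfm`, `phipsii`, `r550_510`).
#' @export
compute_indicator_maps <- function(stack, mask) {
  fr <- stack$frames
  list(
    fvfm = compute_fvfm(fr$Fo, fr$Fm, mask),
    phipsii = compute_phipsii(fr$F, fr$Fm_prime, mask),
    r550_510 = compute_ratio_550_510(fr$R550, fr$R510, mask)
  )
}

#' Summarise an indicator map over its defined pixels
#'
#' Statistics are taken over defined (plant, non-degenerate) pixels only: the
#' pixel set is the full population of the plant region, so `std` is the
#' population standard deviation; quartiles use linear interpolation.
#'
#' @param map An `indicator_map`.
#' @param day Optional day index recorded in the output.
#' @return A one-row tibble with columns `indicator, day, n_pixels, mean,
#'   std, median, q1, q3, min, max`.
#' @export
#' @examples
#' m <- compute_fvfm(matrix(600, 2, 2), matrix(3000, 2, 2), matrix(TRUE, 2, 2))
#' summarize_map(m)
summarize_map <- function(map, day = NA_integer_) {
  if (!inherits(map, "indicator_map")) abort("`map` must be an indicator_map.")
  x <- map$values[is.finite(map$values)]
  if (length(x) == 0L) {
    abort("indicator map has no defined pixels.",
          class = "fluoroscan_empty_mask")
  }
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(
    indicator = map$indicator,
    day = as.integer(day),
    n_pixels = length(x),
    mean = mean(x),
    std = pop_sd(x),
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    min = min(x),
    max = max(x)
  )
}

#' Summarise all indicators of a stack as a tidy tibble
#'
#' @param maps A list of `indicator_map`s as from [compute_indicator_maps()].
#' @inheritParams summarize_map
#' @return A tibble, one row per indicator.
#' @export
summarize_maps <- function(maps, day = NA_integer_) {
  dplyr::bind_rows(purrr::map(maps, summarize_map, day = day))
}

#' Render an indicator map as a pseudo-color PNG
#'
#' Uses a fixed value scale per indicator (0-0.85 for the fluorescence
#' indicators, 0-2.0 for 550/510) rather than per-image autoscaling, so that
#' day-series panels are visually comparable. Undefined pixels render black;
#' a vertical color bar is embedded at the right edge. Output is
#' deterministic: two renders of the same map are byte-identical.
#'
#' @param map An `indicator_map`.
#' @param out_path Destination PNG path.
#' @param n_colors Colormap resolution.
#' @return `out_path`, invisibly.
#' @export
render_pseudocolor <- function(map, out_path, n_colors = 256L) {
  if (!inherits(map, "indicator_map")) abort("`map` must be an indicator_map.")
  scale <- INDICATOR_SCALES[[map$indicator]] %||% range(map$values, na.rm = TRUE)
  pal <- grDevices::hcl.colors(n_colors, "Viridis")
  rgbm <- grDevices::col2rgb(pal) / 255
  h <- nrow(map$values); w <- ncol(map$values)
  idx <- pmin(pmax(
    1L + as.integer(floor((map$values - scale[1]) / (scale[2] - scale[1]) *
                            (n_colors - 1) + 0.5)),
    1L), n_colors)
  img <- array(0, dim = c(h, w + 12L, 3))
  defined <- is.finite(map$values)
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    plane[defined] <- rgbm[ch, idx[defined]]
    img[, seq_len(w), ch] <- plane
  }
  # embedded color bar: 2 px black separator then a 10 px gradient column
  bar_idx <- pmin(pmax(1L + as.integer((n_colors - 1) * rev(seq_len(h) - 1) /
                                         max(h - 1, 1)), 1L), n_colors)
  for (ch in 1:3) {
    img[, w + 3:12, ch] <- matrix(rgbm[ch, bar_idx], h, 10)
  }
  png::writePNG(img, out_path)
  invisible(out_path)
}
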