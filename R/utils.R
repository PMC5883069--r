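#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats approx coef lm quantile rnorm runif sd setNames
NULL

# Map the greenness driver (chroma, unitless in (0, 1]) to the 550/510
# relative reflectance ratio and back. chroma 0.8 <-> ratio 1.6, the healthy
# preset sitting inside the normal range (550/510 above 1.5).
chroma_to_ratio <- function(chroma) 2 * chroma
ratio_to_chroma <- function(ratio) ratio / 2

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

# Radial vignetting multiplier field: 1 at the optical centre, falling
# quadratically to (1 - strength) at the corner. Always in (0, 1].
vignetting_field <- function(nrow, ncol, strength) {
  cy <- (nrow + 1) / 2
  cx <- (ncol + 1) / 2
  rr <- outer((seq_len(nrow) - cy)^2, (seq_len(ncol) - cx)^2, `+`)
  rmax2 <- max(rr)
  if (rmax2 == 0) rmax2 <- 1
  1 - strength * rr / rmax2
}

# Population (not sample) standard deviation: the pixel set is the full
# population of the plant region, not a sample from it.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

matrix_dims_equal <- function(...) {
  dims <- lapply(list(...), dim)
  all(vapply(dims[-1], identical, logical(1), dims[[1]]))
}
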