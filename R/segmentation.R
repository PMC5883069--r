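#' Construct a plant mask
#'
#' @param mask Logical matrix, `TRUE` on plant pixels.
#' @param provenance Which route produced the mask.
#' @return An object of class `plant_mask` with fields `mask`, `provenance`
#'   and `n_plant_pixels`.
#' @export
plant_mask <- function(mask, provenance = c("fluorescence_threshold",
                                            "multispectral_kmeans",
                                            "ground_truth", "manual")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("`mask` must be a logical matrix.")
  }
  structure(list(mask = mask, provenance = provenance,
                 n_plant_pixels = sum(mask)),
            class = "plant_mask")
}

#' @export
print.plant_mask <- function(x, ...) {
  cat(sprintf("<plant_mask> %d x %d px, %d plant pixels (%.1f%%), via %s\n",
              nrow(x$mask), ncol(x$mask), x$n_plant_pixels,
              100 * x$n_plant_pixels / length(x$mask), x$provenance))
  invisible(x)
}

#' Segment plants by thresholding the Fm fluorescence frame
#'
#' The non-plant area barely fluoresces, so the Fm frame separates into a
#' dark background mode and one or more bright plant modes (healthy tissue,
#' and possibly dimmer stressed or necrotic tissue). The threshold is Otsu's
#' method applied to the log-transformed Fm histogram -- the log scale keeps
#' the split between background and plant rather than between dim and bright
#' plant tissue when lesions are present -- floored at the estimated
#' background mean plus five background standard deviations so that a frame
#' with little or no plant material does not split the background noise in
#' two. An empty result is allowed and produces a warning, not an error.
#'
#' @param fm_frame Numeric matrix of Fm counts.
#' @param bit_depth Bit depth used to set the Otsu histogram range.
#' @return A [plant_mask()] with attribute `threshold`.
#' @export
#' @examples
#' fm <- matrix(c(rep(30, 50), rep(2400, 50)), 10, 10)
#' segment_fluorescence_threshold(fm)$n_plant_pixels
segment_fluorescence_threshold <- function(fm_frame, bit_depth = 12L) {
  if (!is.matrix(fm_frame) || length(fm_frame) == 0L) {
    abort("`fm_frame` must be a non-empty matrix.")
  }
  cap <- 2^bit_depth - 1
  rng <- range(fm_frame)
  if (rng[1] == rng[2]) {
    warn("constant Fm frame: empty plant mask.")
    out <- plant_mask(matrix(FALSE, nrow(fm_frame), ncol(fm_frame)),
                      "fluorescence_threshold")
    attr(out, "threshold") <- Inf
    return(out)
  }
  lg <- log1p(pmax(fm_frame, 0))
  thr_otsu <- expm1(EBImage::otsu(lg / log1p(cap), range = c(0, 1),
                                  levels = 2^bit_depth) * log1p(cap))
  bg <- fm_frame[fm_frame <= thr_otsu]
  thr <- max(thr_otsu, mean(bg) + 5 * stats::sd(bg))
  mask <- fm_frame > thr
  if (!any(mask)) warn("fluorescence threshold produced an empty plant mask.")
  out <- plant_mask(mask, "fluorescence_threshold")
  attr(out, "threshold") <- thr
  out
}

# Deterministic farthest-point initialisation for 2-means: a seeded start
# pixel, then the point farthest from it, then the point farthest from that.
farthest_point_centers <- function(x, seed) {
  set.seed(seed)
  i0 <- sample.int(nrow(x), 1)
  d0 <- rowSums(sweep(x, 2, x[i0, ])^2)
  i1 <- which.max(d0)
  d1 <- rowSums(sweep(x, 2, x[i1, ])^2)
  i2 <- which.max(d1)
  rbind(x[i1, ], x[i2, ])
}

#' Segment plants by two-class k-means on the multispectral frames
#'
#' Each pixel is described by the feature vector (R510, R550, R550/R510),
#' standardised to zero mean and unit variance, and clustered into k = 2
#' groups (plant vs background), starting from a deterministic farthest-point
#' initialisation. On small inputs (up to 4096 pixels), where an
#' unstructured feature cloud makes local optima a real risk, additional
#' seeded restarts are run and the partition with the lowest within-cluster
#' sum of squares is kept, so the result matches the exhaustive minimum-SSE
#' 2-partition; on full camera frames the strongly bimodal plant/background
#' structure makes the single deterministic start sufficient (and restarts
#' costly). The cluster with the higher mean 550/510 ratio is labelled plant
#' (vegetation is relatively green); labelling is therefore invariant to
#' which cluster index the algorithm happens to assign.
#'
#' @param r510_frame,r550_frame Reflectance frames, same shape.
#' @param seed Seed for the initialisation; results are deterministic given
#'   the seed.
#' @return A [plant_mask()].
#' @export
segment_kmeans <- function(r510_frame, r550_frame, seed = 1L) {
  if (!matrix_dims_equal(r510_frame, r550_frame)) {
    abort("reflectance frames must share one shape.")
  }
  eps <- 1e-6
  ratio <- r550_frame / pmax(r510_frame, eps)
  feats <- cbind(as.vector(r510_frame), as.vector(r550_frame), as.vector(ratio))
  sds <- apply(feats, 2, stats::sd)
  if (all(sds == 0)) {
    abort("all pixels identical: k-means segmentation is degenerate.",
          class = "fluoroscan_degenerate_input")
  }
  keep <- sds > 0
  z <- scale(feats[, keep, drop = FALSE])
  centers <- farthest_point_centers(z, seed)
  if (all(centers[1, ] == centers[2, ])) {
    abort("fewer than two distinct pixel feature vectors.",
          class = "fluoroscan_degenerate_input")
  }
  km <- tryCatch(
    stats::kmeans(z, centers = centers, iter.max = 100L, algorithm = "Lloyd"),
    error = function(e) stats::kmeans(z, centers = centers, iter.max = 100L)
  )
  if (nrow(z) <= 4096L) {
    km2 <- tryCatch(
      stats::kmeans(z, centers = 2L, nstart = 19L, iter.max = 100L),
      error = function(e) NULL
    )
    if (!is.null(km2) && km2$tot.withinss < km$tot.withinss - 1e-12) km <- km2
  }
  mean_ratio <- tapply(as.vector(ratio), km$cluster, mean)
  plant_cluster <- as.integer(names(which.max(mean_ratio)))
  mask <- matrix(km$cluster == plant_cluster,
                 nrow(r510_frame), ncol(r510_frame))
  plant_mask(mask, "multispectral_kmeans")
}

#' Remove small connected components from a mask
#'
#' Drops 4-connected components smaller than `min_component_area` pixels
#' (noise specks). Idempotent; `min_component_area = 0` is the identity.
#'
#' @param mask A [plant_mask()] or logical matrix.
#' @param min_component_area Minimum surviving component area, pixels.
#' @return A [plant_mask()] with the same provenance.
#' @export
clean_mask <- function(mask, min_component_area = 25L) {
  if (min_component_area < 0) abort("`min_component_area` must be >= 0.")
  pm <- if (inherits(mask, "plant_mask")) mask else plant_mask(mask, "manual")
  if (min_component_area == 0L || pm$n_plant_pixels == 0L) return(pm)
  labels <- EBImage::bwlabel(pm$mask * 1)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_component_area)
  out <- matrix(labels %in% keep & pm$mask, nrow(pm$mask), ncol(pm$mask))
  res <- plant_mask(out, pm$provenance)
  attr(res, "threshold") <- attr(pm, "threshold")
  res
}

#' Jaccard overlap between two masks
#'
#' |A intersect B| / |A union B|; 1 when both masks are empty.
#' @param a,b `plant_mask`s or logical matrices of the same shape.
#' @return A number in [0, 1].
#' @export
mask_jaccard <- function(a, b) {
  ma <- if (inherits(a, "plant_mask")) a$mask else a
  mb <- if (inherits(b, "plant_mask")) b$mask else b
  if (!matrix_dims_equal(ma, mb)) abort("masks must share one shape.")
  u <- sum(ma | mb)
  if (u == 0) return(1)
  sum(ma & mb) / u
}

#' Write a mask as an 8-bit TIFF (0 background / 255 plant)
#' @param mask A [plant_mask()].
#' @param path Destination path.
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "plant_mask")) abort("`mask` must be a plant_mask.")
  tiff::writeTIFF(mask$mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}
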