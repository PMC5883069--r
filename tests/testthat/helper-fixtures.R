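# Small-scene fixtures used across the suite: a 174 x 232 view with 2 plants
# keeps every property loop fast while preserving the full geometry
# (multiple plants, old/new leaves, vignetting).
small_spec <- function(n_plants = 2L) {
  scene_spec(image_height = 174L, image_width = 232L, n_plants = n_plants)
}

healthy_field <- function(seed = 1L, n_plants = 2L) {
  build_scene(small_spec(n_plants), seed = seed)
}

# ground-truth mask from a generator field
truth_mask <- function(field) plant_mask(field$footprint, "ground_truth")

# one measured day: segment by the fluorescence route, compute maps
measure_day <- function(stack, truth = NULL) {
  mask <- clean_mask(segment_fluorescence_threshold(
    stack$frames$Fm, bit_depth = stack$metadata$bit_depth))
  compute_indicator_maps(stack, mask)
}

# full measured trajectory for one stress type on the small scene
measure_trajectory <- function(stress, seed, n_days = 9L) {
  model <- stress_model(stress, n_days = n_days)
  ds <- generate_dataset(small_spec(), model, imaging_model(),
                         days = seq_len(n_days), seed = seed)
  summaries <- vector("list", n_days)
  patch <- numeric(n_days)
  for (i in seq_len(n_days)) {
    maps <- measure_day(ds$stacks[[i]])
    summaries[[i]] <- summarize_maps(maps, day = i)
    patch[i] <- patchiness_score(maps$fvfm)
  }
  list(summaries = dplyr::bind_rows(summaries), patchiness = patch)
}

# independent exhaustive minimum-SSE 2-partition on standardised features;
# returns a 0/1 group vector (enumeration, no clustering library involved)
brute_force_two_partition <- function(z) {
  n <- nrow(z)
  stopifnot(n >= 2, n <= 16)
  best <- NULL
  best_sse <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    sse <- 0
    for (g in 0:1) {
      zz <- z[grp == g, , drop = FALSE]
      ctr <- colMeans(zz)
      sse <- sse + sum(sweep(zz, 2, ctr)^2)
    }
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- grp
    }
  }
  best
}

# the k-means feature construction, repeated here so the oracle comparison
# standardises exactly the same quantities
kmeans_features <- function(r510, r550) {
  ratio <- r550 / pmax(r510, 1e-6)
  feats <- cbind(as.vector(r510), as.vector(r550), as.vector(ratio))
  sds <- apply(feats, 2, stats::sd)
  scale(feats[, sds > 0, drop = FALSE])
}
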