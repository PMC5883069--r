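FRAME_ORDER <- c("Fo", "Fm", "F", "Fm_prime", "R510", "R550")

#' Construct an acquisition frame stack
#'
#' One acquisition consists of six co-registered frames: the four modulated
#' chlorophyll-fluorescence frames Fo (minimal, dark-adapted), Fm (maximal,
#' saturating pulse), F (steady state under actinic light) and Fm' (maximal
#' under light), plus reflectance frames at 510 nm and 550 nm. Counts are
#' non-negative and all frames share one shape.
#'
#' @param frames Named list of six numeric matrices, keys exactly
#'   `Fo, Fm, F, Fm_prime, R510, R550`.
#' @param metadata A [stack_metadata()].
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, metadata = stack_metadata()) {
  if (!is.list(frames)) abort("`frames` must be a named list of matrices.")
  missing <- setdiff(FRAME_ORDER, names(frames))
  if (length(missing) > 0) {
    abort(sprintf("missing frame %s", paste(missing, collapse = ", ")),
          class = "fluoroscan_format_error")
  }
  extra <- setdiff(names(frames), FRAME_ORDER)
  if (length(extra) > 0) {
    abort(sprintf("unexpected frame key(s): %s", paste(extra, collapse = ", ")),
          class = "fluoroscan_format_error")
  }
  frames <- frames[FRAME_ORDER]
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1)))) {
    abort("all frames must share one shape.", class = "fluoroscan_format_error")
  }
  if (any(vapply(frames, function(f) any(f < 0), logical(1)))) {
    abort("counts must be non-negative.", class = "fluoroscan_format_error")
  }
  structure(list(frames = frames, metadata = metadata), class = "frame_stack")
}

#' Acquisition metadata
#'
#' Records the protocol context of one acquisition: position on the bed scan
#' grid, day index, the light levels of the measuring / actinic / saturating
#' phases, and the optical wavelengths (460 nm excitation LED, fluorescence
#' detected above 650 nm, spectral bands 510 and 550 nm). Wavelengths are
#' fixed by the instrument protocol.
#'
#' @param position Integer (x, y) tile indices on the bed grid (0-based).
#' @param day Day index of the acquisition.
#' @param light_levels Named vector, umol photons m^-2 s^-1.
#' @param bit_depth Camera bit depth (12-bit scientific CCD).
#' @return An object of class `stack_metadata`.
#' @export
stack_metadata <- function(position = c(0L, 0L), day = 1L,
                           light_levels = c(measuring = 0.1, actinic = 200,
                                            saturating = 6000),
                           bit_depth = 12L) {
  if (any(position < 0)) abort("grid position indices must be >= 0.")
  structure(
    list(position = as.integer(position), day = as.integer(day),
         light_levels = light_levels,
         wavelengths = list(excitation_nm = 460, detection_above_nm = 650,
                            spectral_nm = c(510, 550)),
         bit_depth = as.integer(bit_depth)),
    class = "stack_metadata"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d x %d px, frames %s, day %d, position (%d, %d)\n",
              d[1], d[2], paste(FRAME_ORDER, collapse = "/"),
              x$metadata$day, x$metadata$position[1], x$metadata$position[2]))
  invisible(x)
}

#' Write / read an acquisition stack
#'
#' The six frames are written as a multi-page TIFF with 16-bit unsigned
#' samples in the fixed page order Fo, Fm, F, Fm', R510, R550; counts are
#' rounded to the nearest integer on write (the camera ADC emits integer
#' counts, so generated stacks with noise enabled round-trip byte-losslessly).
#' Metadata travels in a JSON sidecar next to the image file
#' (`<path>.json`), keeping the image a plain standard container.
#'
#' @param stack A [frame_stack()].
#' @param path Destination TIFF path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns a
#'   `frame_stack`.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "frame_stack")) abort("`stack` must be a frame_stack.")
  pages <- lapply(stack$frames, function(f) {
    f <- round(f)
    if (any(f > 65535)) abort("counts exceed 16-bit range.")
    f / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  md <- stack$metadata
  jsonlite::write_json(
    list(position = md$position, day = md$day,
         light_levels = as.list(md$light_levels),
         wavelengths = md$wavelengths, bit_depth = md$bit_depth,
         frame_order = FRAME_ORDER),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) < length(FRAME_ORDER)) {
    abort(sprintf("missing frame %s",
                  paste(FRAME_ORDER[seq(length(pages) + 1, length(FRAME_ORDER))],
                        collapse = ", ")),
          class = "fluoroscan_format_error")
  }
  if (length(pages) > length(FRAME_ORDER)) {
    abort("too many pages for a six-frame acquisition stack.",
          class = "fluoroscan_format_error")
  }
  frames <- setNames(lapply(pages, function(p) {
    storage.mode(p) <- "double"
    p
  }), FRAME_ORDER)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    abort(sprintf("missing metadata sidecar: %s", sp),
          class = "fluoroscan_format_error")
  }
  md <- jsonlite::read_json(sp, simplifyVector = TRUE)
  required <- c("position", "day", "light_levels", "bit_depth")
  miss <- setdiff(required, names(md))
  if (length(miss) > 0) {
    abort(sprintf("malformed metadata: missing %s", paste(miss, collapse = ", ")),
          class = "fluoroscan_format_error")
  }
  frame_stack(frames, stack_metadata(
    position = md$position, day = md$day,
    light_levels = unlist(md$light_levels), bit_depth = md$bit_depth
  ))
}

#' Stitch per-position stacks from the bed scan into one mosaic
#'
#' The monitoring system images disjoint positions of the seedling bed by
#' scanning in x and y; tiles are abutted frame-wise (no overlap, no
#' blending) into a mosaic of shape (rows * tile_h, cols * tile_w). Input
#' order is irrelevant: placement is driven by each stack's grid position.
#'
#' @param stacks List of `frame_stack`s whose metadata positions form a
#'   complete rectangular grid of identically shaped tiles.
#' @return A single `frame_stack` covering the scanned area, with position
#'   (0, 0).
#' @export
stitch_mosaic <- function(stacks) {
  if (length(stacks) == 0L) abort("no stacks to stitch.")
  pos <- t(vapply(stacks, function(s) s$metadata$position, integer(2)))
  xs <- sort(unique(pos[, 1])); ys <- sort(unique(pos[, 2]))
  if (!identical(xs, seq(0L, max(pos[, 1]))) ||
      !identical(ys, seq(0L, max(pos[, 2])))) {
    abort("grid positions must start at (0, 0) with no gaps.",
          class = "fluoroscan_grid_error")
  }
  want <- expand.grid(x = xs, y = ys)
  key <- paste(pos[, 1], pos[, 2])
  wkey <- paste(want$x, want$y)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate grid cell(s): %s",
                  paste(unique(key[duplicated(key)]), collapse = "; ")),
          class = "fluoroscan_grid_error")
  }
  missing <- setdiff(wkey, key)
  if (length(missing) > 0) {
    abort(sprintf("missing grid cell(s): (%s)",
                  paste(missing, collapse = "), (")),
          class = "fluoroscan_grid_error")
  }
  d <- dim(stacks[[1]]$frames[[1]])
  same <- vapply(stacks, function(s) identical(dim(s$frames[[1]]), d), logical(1))
  if (!all(same)) abort("all tiles must share one shape.",
                        class = "fluoroscan_grid_error")
  th <- d[1]; tw <- d[2]
  mh <- th * length(ys); mw <- tw * length(xs)
  frames <- setNames(lapply(FRAME_ORDER, function(k) matrix(0, mh, mw)),
                     FRAME_ORDER)
  for (i in seq_along(stacks)) {
    px <- pos[i, 1]; py <- pos[i, 2]
    rows <- py * th + seq_len(th)
    cols <- px * tw + seq_len(tw)
    for (k in FRAME_ORDER) frames[[k]][rows, cols] <- stacks[[i]]$frames[[k]]
  }
  md <- stacks[[1]]$metadata
  frame_stack(frames, stack_metadata(position = c(0L, 0L), day = md$day,
                                     light_levels = md$light_levels,
                                     bit_depth = md$bit_depth))
}
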