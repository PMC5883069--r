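#' Configure a monitoring pipeline run
#'
#' A validated flat configuration for [run_pipeline()]: where to write, which
#' scene/stress to simulate (or which directory of acquisitions to read),
#' which segmentation route to use, threshold overrides, seed and log level.
#' Unknown keys are rejected; the effective configuration is echoed as JSON
#' into the output directory so every output is traceable.
#'
#' @param out_dir Output directory.
#' @param input_dir Optional directory of existing acquisitions (one
#'   `dayNN.tif` + sidecar per day, as written by [generate_dataset()]);
#'   when `NULL` the scene is simulated.
#' @param stress Stress type to simulate (ignored when reading).
#' @param days Number of monitored days.
#' @param seed Master seed for simulation and segmentation.
#' @param segmentation_method `"threshold"` (fluorescence route) or
#'   `"kmeans"` (multispectral route).
#' @param spec,imaging,ranges,cfg Optional component overrides
#'   ([scene_spec()], [imaging_model()], [normal_ranges()], [rule_cfg()]).
#' @param render_png Write pseudo-color PNG maps per day.
#' @param log_level `"info"` or `"quiet"`.
#' @param ... Unknown keys: rejected with an error.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL,
                            stress = c("none", "drought",
                                       "nitrogen_deficiency", "disease"),
                            days = 9L,
                            seed = 42L,
                            segmentation_method = c("threshold", "kmeans"),
                            spec = scene_spec(),
                            imaging = imaging_model(),
                            ranges = normal_ranges(),
                            cfg = rule_cfg(),
                            render_png = FALSE,
                            log_level = c("info", "quiet"),
                            ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(names(extra), collapse = ", ")))
  }
  stress <- match.arg(stress)
  segmentation_method <- match.arg(segmentation_method)
  log_level <- match.arg(log_level)
  structure(
    list(out_dir = out_dir, input_dir = input_dir, stress = stress,
         days = as.integer(days), seed = as.integer(seed),
         segmentation_method = segmentation_method,
         spec = spec, imaging = imaging, ranges = ranges, cfg = cfg,
         render_png = isTRUE(render_png), log_level = log_level),
    class = "pipeline_config"
  )
}

pipeline_log <- function(con, level, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  writeLines(line, con)
  if (level == "info") inform(msg)
}

with_stage <- function(stage, what, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed on %s: %s",
                  stage, what, conditionMessage(e)),
          class = "fluoroscan_stage_error", parent = e)
  })
}

#' Run the full monitoring pipeline
#'
#' simulate (or read) -> segment -> indicator maps -> summaries -> diagnose.
#' Produces a tidy summary CSV (`summaries.csv`: day, position, indicator,
#' mean, std, median, q1, q3, min, max, n_pixels), a diagnosis report
#' (`diagnosis.json`), optional pseudo-color PNGs, a run log and a config
#' echo (`config.json`). Identical config + seed give byte-identical CSV and
#' JSON outputs. Stage errors propagate with the stage name and the input
#' they failed on.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summaries` (tibble), `diagnosis`
#'   (`stress_diagnosis`), `patchiness` (per-day scores), `masks`, and
#'   `paths` of all written artifacts.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(tempfile("run"), stress = "none", days = 3,
#'                        spec = scene_spec(image_height = 120,
#'                                          image_width = 160, n_plants = 1),
#'                        log_level = "quiet")
#' res <- run_pipeline(cfg)
#' res$summaries
#' }
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config.")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  logf <- function(msg) pipeline_log(con, config$log_level, msg)

  echo <- list(stress = config$stress, days = config$days, seed = config$seed,
               segmentation_method = config$segmentation_method,
               input_dir = config$input_dir,
               scene = unclass(config$spec),
               ranges = unclass(config$ranges), rules = unclass(config$cfg))
  jsonlite::write_json(echo, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  if (is.null(config$input_dir)) {
    logf(sprintf("simulating %d-day %s series (seed %d)",
                 config$days, config$stress, config$seed))
    model <- stress_model(config$stress, n_days = config$days)
    ds <- with_stage("simulate", sprintf("%s series", config$stress),
                     generate_dataset(config$spec, model, config$imaging,
                                      days = seq_len(config$days),
                                      seed = config$seed))
    stacks <- ds$stacks
    days <- ds$days
  } else {
    files <- sort(list.files(config$input_dir, pattern = "^day[0-9]+\\.tif$",
                             full.names = TRUE))
    if (length(files) == 0L) {
      abort(sprintf("no acquisition stacks found in %s", config$input_dir))
    }
    stacks <- lapply(files, function(f) with_stage("read", f, read_stack(f)))
    days <- vapply(stacks, function(s) s$metadata$day, integer(1))
    logf(sprintf("read %d acquisition(s) from %s", length(stacks),
                 config$input_dir))
  }

  summaries <- list()
  patchiness <- numeric(length(days))
  masks <- vector("list", length(days))
  png_paths <- character(0)
  for (i in seq_along(days)) {
    d <- days[i]
    what <- sprintf("day %d", d)
    stk <- stacks[[i]]
    mask <- with_stage("segment", what, {
      if (config$segmentation_method == "threshold") {
        clean_mask(segment_fluorescence_threshold(
          stk$frames$Fm, bit_depth = stk$metadata$bit_depth))
      } else {
        clean_mask(segment_kmeans(stk$frames$R510, stk$frames$R550,
                                  seed = config$seed + d))
      }
    })
    masks[[i]] <- mask
    maps <- with_stage("indicators", what, compute_indicator_maps(stk, mask))
    summaries[[i]] <- with_stage("summarize", what,
                                 summarize_maps(maps, day = d))
    patchiness[i] <- with_stage(
      "patchiness", what,
      patchiness_score(maps$fvfm, config$cfg$impairment_threshold))
    if (config$render_png) {
      for (ind in names(maps)) {
        p <- file.path(config$out_dir, sprintf("day%02d_%s.png", d, ind))
        with_stage("render", what, render_pseudocolor(maps[[ind]], p))
        png_paths <- c(png_paths, p)
      }
    }
    logf(sprintf("day %d: %d plant pixels, patchiness %.3f",
                 d, mask$n_plant_pixels, patchiness[i]))
  }

  summary_tbl <- dplyr::bind_rows(summaries) |>
    dplyr::mutate(position = "0,0", .after = "day")
  csv_path <- file.path(config$out_dir, "summaries.csv")
  readr::write_csv(summary_tbl, csv_path)

  diagnosis <- with_stage("diagnose", "trajectory",
                          classify_stress(summary_tbl, patchiness,
                                          config$ranges, config$cfg))
  json_path <- file.path(config$out_dir, "diagnosis.json")
  write_diagnosis(diagnosis, json_path)
  logf(sprintf("diagnosis: %s (confidence %.2f)",
               diagnosis$label, diagnosis$confidence))

  invisible(list(
    summaries = summary_tbl, diagnosis = diagnosis,
    patchiness = patchiness, masks = masks,
    paths = list(summaries = csv_path, diagnosis = json_path,
                 config = file.path(config$out_dir, "config.json"),
                 log = log_path, png = png_paths)
  ))
}
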