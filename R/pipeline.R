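# End-to-end orchestration: batch processing of an image folder into a
# measurement table, longitudinal summaries and t-test reports.

#' Pipeline configuration
#'
#' Assembles and validates the full parameter set. Values can come from a
#' YAML file (nested sections `input`, `preprocess`, `segment`,
#' `aggregate`) with explicit arguments overriding file values.
#'
#' @param file Optional YAML config path.
#' @param ... Overrides as `section.key = value` pairs, e.g.
#'   `segment.threshold_correction = 0.7`.
#' @return A list of class `pipeline_config` with elements `input`
#'   (folder, extension, metadata_pattern, metadata_csv, on_parse_error),
#'   `preprocess` ([preprocess_params()]), `segment`
#'   ([segmentation_params()]), `aggregate` (control_condition,
#'   baseline_day, welch, fdr).
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- list(
    input = list(folder = NULL, extension = ".tiff",
                 metadata_pattern = default_metadata_pattern(),
                 metadata_csv = NULL, on_parse_error = "skip"),
    preprocess = list(gray_weights = c(1, 1, 1) / 3, sharpen_amount = 1,
                      sharpen_sigma = 1, gaussian_sigma = 2),
    segment = list(),
    aggregate = list(control_condition = NULL, baseline_day = 1L,
                     welch = FALSE, fdr = FALSE))
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    for (sec in intersect(names(y), names(cfg)))
      cfg[[sec]][names(y[[sec]])] <- y[[sec]]
  }
  dots <- list(...)
  for (nm in names(dots)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !parts[1L] %in% names(cfg))
      stop("unknown config key: ", nm)
    cfg[[parts[1L]]][[parts[2L]]] <- dots[[nm]]
  }
  if (!cfg$input$on_parse_error %in% c("skip", "abort"))
    stop("input.on_parse_error must be 'skip' or 'abort'")
  cfg$preprocess <- do.call(preprocess_params, cfg$preprocess)
  cfg$segment <- do.call(segmentation_params, cfg$segment)
  structure(cfg, class = "pipeline_config")
}

#' Process one loaded image through the pipeline
#'
#' preprocess -> segment -> measure. Returns the measurement rows plus the
#' intermediate stage images for inspection.
#'
#' @param image A `spheroid_image` (or matrix/array).
#' @param config A [pipeline_config()].
#' @return List with `measurements` (data.frame), `stages` (named list of
#'   matrices), `label_map`, `threshold`, `raw_threshold`.
#' @export
process_image <- function(image, config = pipeline_config()) {
  pre <- preprocess_image(image, config$preprocess)
  seg <- segment_image(pre, config$segment)
  meas <- measure_objects(seg$label_map, config$segment)
  list(measurements = meas,
       stages = c(pre, list(labels = seg$label_map$labels)),
       label_map = seg$label_map,
       threshold = seg$threshold, raw_threshold = seg$raw_threshold)
}

#' Run the pipeline over an image folder
#'
#' Lists and loads every matching TIFF, parses filename metadata, runs
#' preprocess/segment/measure per image, joins optional sidecar
#' day/condition metadata, and (when a control condition is configured or
#' derivable) produces per-condition/day summaries, control-normalized
#' means and per-day t-tests against the control. Per-image failures are
#' logged and skipped unless `strict`.
#'
#' @param folder Input folder (overrides `config$input$folder`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory to write `measurements.csv`,
#'   `summary.csv` and `ttests.csv` into.
#' @param strict Abort on the first per-image failure.
#' @param verbose Log one line per image to stderr.
#' @return An object of class `spheroid_experiment`: list with
#'   `measurements`, `summaries`, `ttests`, `config`, `skipped`.
#' @export
run_pipeline <- function(folder = NULL, config = pipeline_config(),
                         out_dir = NULL, strict = FALSE, verbose = FALSE) {
  folder <- folder %||% config$input$folder
  if (is.null(folder)) stop("no input folder configured")
  if (!dir.exists(folder))
    stop(structure(class = c("input_error", "error", "condition"),
                   list(message = paste0("not a directory: ", folder),
                        call = sys.call(-1))))
  files <- list_inputs(folder, config$input$extension)
  files <- files[basename(files) != "metadata.csv"]
  if (length(files) == 0L)
    stop(structure(class = c("input_error", "error", "condition"),
                   list(message = paste0("no input images in ", folder),
                        call = sys.call(-1))))
  sidecar <- NULL
  csv_path <- config$input$metadata_csv %||% file.path(folder, "metadata.csv")
  if (file.exists(csv_path)) sidecar <- read_metadata_csv(csv_path)
  rows <- list(); skipped <- character()
  for (f in files) {
    res <- tryCatch({
      meta <- parse_metadata(basename(f), config$input$metadata_pattern)
      img <- load_tiff(f)
      pr <- process_image(img, config)
      m <- pr$measurements
      if (verbose)
        message(sprintf("[spheromorph] %s: %d object(s), threshold %.4f",
                        basename(f), nrow(m),
                        if (is.na(pr$threshold)) NA else pr$threshold))
      if (nrow(m) == 0L) NULL
      else cbind(data.frame(experiment = meta$experiment,
                            spheroid_id = meta$spheroid_id,
                            condition = meta$condition %||% NA_character_,
                            day = meta$day, stringsAsFactors = FALSE), m)
    }, error = function(e) {
      if (strict || inherits(e, "metadata_parse_error") &&
          config$input$on_parse_error == "abort") stop(e)
      warning("skipping ", basename(f), ": ", conditionMessage(e),
              call. = FALSE)
      skipped <<- c(skipped, basename(f))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  meas <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(ncol = length(measurement_columns),
                                      nrow = 0)), measurement_columns)
  if (!is.null(sidecar) && nrow(meas)) {
    i <- match(meas$spheroid_id, sidecar$spheroid_id)
    fill_day <- is.na(meas$day) & !is.na(i)
    fill_cond <- is.na(meas$condition) & !is.na(i)
    meas$day[fill_day] <- sidecar$day[i[fill_day]]
    meas$condition[fill_cond] <- sidecar$condition[i[fill_cond]]
  }
  summaries <- NULL; ttests <- NULL
  if (nrow(meas) && !anyNA(meas$condition) && !anyNA(meas$day)) {
    summaries <- summarize_scores(meas)
    control <- config$aggregate$control_condition
    if (is.null(control)) control <- summaries$condition[1L]
    if (control %in% summaries$condition) {
      base_day <- config$aggregate$baseline_day
      if (any(summaries$condition == control & summaries$day == base_day))
        summaries <- normalize_to_control(summaries, control, base_day)
      ttests <- compare_all_to_control(meas, control,
                                       welch = isTRUE(config$aggregate$welch),
                                       fdr = isTRUE(config$aggregate$fdr))
    }
  }
  out <- structure(list(measurements = meas, summaries = summaries,
                        ttests = ttests, config = config, skipped = skipped),
                   class = "spheroid_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_csv(meas, file.path(out_dir, "measurements.csv"))
    if (!is.null(summaries))
      utils::write.csv(format_float_df(summaries),
                       file.path(out_dir, "summary.csv"), row.names = FALSE)
    if (!is.null(ttests))
      utils::write.csv(format_float_df(ttests),
                       file.path(out_dir, "ttests.csv"), row.names = FALSE)
  }
  out
}

format_float_df <- function(d) {
  for (j in seq_along(d)) if (is.double(d[[j]])) d[[j]] <- signif(d[[j]], 6)
  d
}

#' Process a single image, optionally writing stage images
#'
#' Runs the full chain on one file and, when `debug_dir` is given, writes
#' the seven per-stage images: (i) input, (ii) grayscale, (iii) sharpened,
#' (iv) smoothed, (v) edge magnitude, (vi) object labels, (vii) object
#' outlines over the input.
#'
#' @param path Image path.
#' @param config A [pipeline_config()].
#' @param debug_dir Optional directory for stage TIFFs.
#' @return The [process_image()] result, with `metadata` attached when the
#'   filename parses.
#' @export
run_single <- function(path, config = pipeline_config(), debug_dir = NULL) {
  img <- load_tiff(path)
  res <- process_image(img, config)
  res$metadata <- tryCatch(parse_metadata(basename(path),
                                          config$input$metadata_pattern),
                           error = function(e) NULL)
  if (!is.null(debug_dir)) {
    dir.create(debug_dir, recursive = TRUE, showWarnings = FALSE)
    gray_in <- to_grayscale(img, config$preprocess$gray_weights)
    lab <- res$label_map$labels
    n <- max(1L, res$label_map$n_objects)
    outline <- gray_in
    if (res$label_map$n_objects > 0L)
      for (ct in EBImage::ocontour(lab)) outline[ct + 1L] <- 1
    stages <- list(`stage1_input` = gray_in,
                   `stage2_gray` = res$stages$gray,
                   `stage3_sharpened` = res$stages$sharpened,
                   `stage4_smoothed` = res$stages$smoothed,
                   `stage5_edges` = res$stages$edges,
                   `stage6_objects` = lab / n,
                   `stage7_outlines` = outline)
    for (nm in names(stages))
      write_tiff(stages[[nm]], file.path(debug_dir, paste0(nm, ".tiff")))
  }
  res
}

#' @export
print.spheroid_experiment <- function(x, ...) {
  cat("spheroid_experiment\n")
  cat(sprintf("  %d object(s) measured across %d image(s); %d skipped\n",
              nrow(x$measurements),
              length(unique(x$measurements$spheroid_id)),
              length(x$skipped)))
  if (!is.null(x$summaries)) {
    cat("  per-condition/day mean mesenchymal scores:\n")
    print(x$summaries, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.spheroid_experiment <- function(object, ...) {
  list(n_objects = nrow(object$measurements),
       n_images = length(unique(object$measurements$spheroid_id)),
       n_skipped = length(object$skipped),
       summaries = object$summaries,
       ttests = object$ttests)
}
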