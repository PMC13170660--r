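## File formats: trace CSV (time column + one column per ROI), multi-page
## TIFF image bundles with a JSON channel manifest, labelled ROI-mask TIFF,
## JSON truth/report files, YAML pipeline configuration.

format_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("iq_format_error", "error")))
}

#' Write / read a fluorescence trace CSV
#'
#' Layout: first column `time_s` (frame midpoint-free, frame k at
#' `(k-1)/sampling_rate`), then one column per ROI, header row of ROI
#' identifiers. `read_trace_csv(write_trace_csv(x))` is the identity on
#' values within float round-trip.
#'
#' @param traces A `FluorescenceTraceSet`.
#' @param path CSV file path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `FluorescenceTraceSet`.
#' @export
write_trace_csv <- function(traces, path) {
  stopifnot(inherits(traces, "FluorescenceTraceSet"))
  df <- data.frame(time_s = (seq_len(ncol(traces$F)) - 1L) /
                     traces$sampling_rate,
                   t(traces$F), check.names = FALSE)
  names(df) <- c("time_s", traces$roi_ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param group_label,timepoint_label Optional labels attached to the read
#'   trace set.
#' @export
read_trace_csv <- function(path, group_label = NA_character_,
                           timepoint_label = NA_character_) {
  if (!file.exists(path)) format_error("no such file: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) format_error("unreadable CSV: ",
                                                  conditionMessage(e)))
  if (nrow(df) < 2L || ncol(df) < 2L) {
    format_error("trace CSV needs a time column, >= 1 ROI column and >= 2 rows")
  }
  if (!(names(df)[1] %in% c("time_s", "frame"))) {
    format_error("first column must be 'time_s' or 'frame', got '",
                 names(df)[1], "'")
  }
  roi_ids <- names(df)[-1]
  if (anyDuplicated(roi_ids)) {
    format_error("duplicated ROI id: ", roi_ids[duplicated(roi_ids)][1])
  }
  vals <- as.matrix(df[-1])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)
    format_error("non-finite or non-numeric value at row ",
                 if (length(bad)) bad[1, 1] else NA)
  }
  sampling_rate <- if (names(df)[1] == "time_s") {
    dt <- diff(df[[1]])
    if (any(dt <= 0)) format_error("time column must be strictly increasing")
    1 / stats::median(dt)
  } else {
    1
  }
  fluorescence_trace_set(t(vals), sampling_rate, roi_ids = roi_ids,
                         group_label = group_label,
                         timepoint_label = timepoint_label)
}

#' Write / read a multi-channel image bundle (TIFF + JSON manifest)
#'
#' Channels are stored as pages of a 32-bit float TIFF scaled to `[0, 1]`;
#' the sidecar manifest records each channel's page index (0-based), its
#' intensity scale factor, and the pixel size, so intensities round-trip in
#' their original units.
#'
#' @param image A `LabeledImage`.
#' @param tiff_path,manifest_path Output paths.
#' @param required_roles For reading: channel roles that must be present.
#' @return `write_image_bundle` returns `tiff_path` invisibly;
#'   `read_image_bundle` a `LabeledImage`.
#' @export
write_image_bundle <- function(image, tiff_path, manifest_path) {
  stopifnot(inherits(image, "LabeledImage"))
  scales <- vapply(image$channels, function(ch) max(ch, 1), numeric(1))
  pages <- Map(function(ch, s) ch / s, image$channels, scales)
  tiff::writeTIFF(unname(pages), tiff_path, bits.per.sample = 32L)
  manifest <- list(
    channels = Map(function(i, s) list(page = i - 1L, scale = s),
                   seq_along(image$channels), as.list(scales)),
    pixel_size = image$pixel_size)
  names(manifest$channels) <- names(image$channels)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(tiff_path)
}

#' @rdname write_image_bundle
#' @export
read_image_bundle <- function(tiff_path, manifest_path,
                              required_roles = character()) {
  if (!file.exists(tiff_path)) format_error("no such file: ", tiff_path)
  if (!file.exists(manifest_path)) format_error("no such file: ", manifest_path)
  manifest <- jsonlite::read_json(manifest_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  missing <- setdiff(required_roles, names(manifest$channels))
  if (length(missing)) {
    format_error("manifest lacks required channel role(s): ",
                 paste(missing, collapse = ", "))
  }
  channels <- lapply(manifest$channels, function(ch) {
    page <- ch$page + 1L
    if (page < 1L || page > length(pages)) {
      format_error("manifest page index ", ch$page, " out of range")
    }
    pages[[page]] * ch$scale
  })
  shapes <- unique(vapply(channels, function(ch) paste(dim(ch), collapse = "x"),
                          character(1)))
  if (length(shapes) != 1L) format_error("channel pages differ in shape")
  labeled_image(channels, pixel_size = manifest$pixel_size)
}

#' Write / read soma and nucleus ROI masks as a labelled TIFF
#'
#' Single 16-bit page: 0 background, 1 soma cytoplasm, 2 nucleus (the soma
#' mask is the union of labels 1 and 2, so the nucleus is contained in the
#' soma by construction).
#'
#' @param rois A `RoiSet`.
#' @param path TIFF file path.
#' @param image_shape For reading: optional `c(nrow, ncol)` the mask must
#'   match.
#' @return `write_roi_masks` returns `path` invisibly; `read_roi_masks` a
#'   `RoiSet` with provenance `"manual"`.
#' @export
write_roi_masks <- function(rois, path) {
  stopifnot(inherits(rois, "RoiSet"))
  lab <- matrix(0L, nrow(rois$soma_mask), ncol(rois$soma_mask))
  lab[rois$soma_mask] <- 1L
  lab[rois$nucleus_mask] <- 2L
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_roi_masks
#' @export
read_roi_masks <- function(path, image_shape = NULL) {
  if (!file.exists(path)) format_error("no such file: ", path)
  lab <- round(tiff::readTIFF(path) * 65535)
  if (!is.null(image_shape) && !identical(dim(lab), as.integer(image_shape))) {
    format_error("ROI mask shape (", paste(dim(lab), collapse = "x"),
                 ") does not match image shape (",
                 paste(image_shape, collapse = "x"), ")")
  }
  roi_set(soma_mask = lab >= 1, nucleus_mask = lab == 2,
          provenance = "manual")
}

## Pipeline configuration ----------------------------------------------------

#' Default pipeline configuration
#'
#' All stage parameters in one validated, YAML-serialisable list: baseline
#' window, template grid, detection thresholds, segmentation parameters,
#' binding model, master seed, log level.
#'
#' @return A `PipelineConfig` list.
#' @export
default_pipeline_config <- function() {
  structure(list(
    window_s = 60,
    similarity_threshold = 0.75,
    min_amplitude = 0.01,
    template = list(rise_taus = c(0.05, 0.1, 0.2),
                    decay_taus = c(0.3, 0.6, 1.2),
                    template_len_s = 3),
    segmentation = list(smoothing_sigma = 1, min_area_px = 2),
    binding = list(model = "one_site"),
    master_seed = 1L,
    log_level = "info"),
    class = "PipelineConfig")
}

validate_config <- function(cfg) {
  check_number(cfg$window_s, "window_s", lower = 0, strict_lower = TRUE)
  check_number(cfg$similarity_threshold, "similarity_threshold", lower = -1,
               upper = 1)
  check_number(cfg$min_amplitude, "min_amplitude", lower = 0)
  if (any(outer(cfg$template$decay_taus, cfg$template$rise_taus, "<="))) {
    stop_invalid("template grid contains decay_tau <= rise_tau")
  }
  check_number(cfg$template$template_len_s, "template_len_s", lower = 0,
               strict_lower = TRUE)
  check_number(cfg$segmentation$smoothing_sigma, "smoothing_sigma", lower = 0)
  check_number(cfg$segmentation$min_area_px, "min_area_px", lower = 0)
  if (!cfg$binding$model %in% c("one_site", "half_max_printed")) {
    stop_invalid("unknown binding model: ", cfg$binding$model)
  }
  check_number(cfg$master_seed, "master_seed")
  if (!cfg$log_level %in% c("debug", "info", "warning")) {
    stop_invalid("log_level must be debug/info/warning")
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration (YAML)
#'
#' The configuration is schema-validated at load (every parameter checked
#' against its stage's preconditions) and round-trips
#' read -> write -> read identically.
#'
#' @param path YAML file path.
#' @param cfg A `PipelineConfig`.
#' @return `read_pipeline_config` returns a validated `PipelineConfig`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) format_error("no such file: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  for (k in names(raw)) {
    if (!k %in% names(cfg)) stop_invalid("unknown config key: ", k)
    if (is.list(cfg[[k]])) {
      for (k2 in names(raw[[k]])) {
        if (!k2 %in% names(cfg[[k]])) {
          stop_invalid("unknown config key: ", k, ".", k2)
        }
        cfg[[k]][[k2]] <- raw[[k]][[k2]]
      }
    } else {
      cfg[[k]] <- raw[[k]]
    }
  }
  validate_config(cfg)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## Logging -------------------------------------------------------------------

iq_log <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warning = 3)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
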