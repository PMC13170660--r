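## Raw fluorescence -> dF/F0 with a percentile-window baseline.

#' Construct a raw fluorescence trace set
#'
#' Container for per-ROI raw fluorescence time series as exported from
#' ROI-based movie measurement (rows = ROIs, columns = frames).
#'
#' @param F Numeric matrix `[roi x frame]` of raw fluorescence, arbitrary
#'   units; all values finite; at least 2 frames.
#' @param sampling_rate Hz (`> 0`).
#' @param roi_ids Character vector of ROI identifiers (unique); default
#'   `"roi1"`, `"roi2"`, ...
#' @param group_label,timepoint_label Optional free-text labels carried
#'   through to rate tables.
#' @return A `FluorescenceTraceSet` object.
#' @export
fluorescence_trace_set <- function(F, sampling_rate, roi_ids = NULL,
                                   group_label = NA_character_,
                                   timepoint_label = NA_character_) {
  if (!is.matrix(F) || !is.numeric(F)) stop_invalid("F must be a numeric matrix")
  if (ncol(F) < 2L) stop_invalid("need at least 2 frames")
  if (any(!is.finite(F))) {
    stop(errorCondition("non-finite fluorescence values; no imputation is performed",
                        class = c("iq_format_error", "error")))
  }
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  if (is.null(roi_ids)) roi_ids <- paste0("roi", seq_len(nrow(F)))
  if (length(roi_ids) != nrow(F)) stop_invalid("roi_ids length != nrow(F)")
  if (anyDuplicated(roi_ids)) stop_invalid("duplicated roi_ids")
  rownames(F) <- roi_ids
  structure(
    list(F = F, sampling_rate = sampling_rate, roi_ids = as.character(roi_ids),
         group_label = group_label, timepoint_label = timepoint_label),
    class = "FluorescenceTraceSet")
}

#' @export
print.FluorescenceTraceSet <- function(x, ...) {
  cat(sprintf("FluorescenceTraceSet: %d ROIs x %d frames at %g Hz (%.1f s)\n",
              nrow(x$F), ncol(x$F), x$sampling_rate,
              ncol(x$F) / x$sampling_rate))
  invisible(x)
}

# indices of the tiled baseline windows for a trace of n frames
baseline_windows <- function(n_frames, window_frames) {
  starts <- seq(1L, n_frames, by = window_frames)
  wins <- lapply(starts, function(s) s:min(s + window_frames - 1L, n_frames))
  last <- wins[[length(wins)]]
  if (length(wins) > 1L && length(last) < window_frames / 2) {
    # trailing fragment shorter than half a window: merge into previous
    wins[[length(wins) - 1L]] <- c(wins[[length(wins) - 1L]], last)
    wins[[length(wins)]] <- NULL
  }
  wins
}

#' Baseline fluorescence F0 from tiled percentile windows
#'
#' The trace is tiled into consecutive non-overlapping windows of
#' `window_s` seconds (a trailing partial window at least half a window long
#' is kept as its own window, otherwise merged into the previous one); the
#' 50th percentile of each window is taken (linear-interpolation quantile)
#' and F0 is the mean of the window percentiles — one scalar per ROI.
#'
#' @param traces A `FluorescenceTraceSet`.
#' @param window_s Window length in seconds (default 60); trace duration
#'   must be at least one window.
#' @return Named numeric vector of F0 values (one per ROI, `> 0`).
#' @export
compute_baseline <- function(traces, window_s = 60) {
  stopifnot(inherits(traces, "FluorescenceTraceSet"))
  check_number(window_s, "window_s", lower = 0, strict_lower = TRUE)
  n <- ncol(traces$F)
  duration <- n / traces$sampling_rate
  if (duration < window_s) {
    stop(errorCondition(
      sprintf("trace duration (%.1f s) shorter than baseline window (%g s)",
              duration, window_s),
      class = c("iq_window_too_long", "error")))
  }
  wf <- floor(window_s * traces$sampling_rate)
  wins <- baseline_windows(n, wf)
  F0 <- apply(traces$F, 1L, function(x) {
    mean(vapply(wins, function(ix) percentile(x[ix], 0.5), numeric(1)))
  })
  if (any(F0 <= 0)) {
    stop(errorCondition("non-positive baseline F0",
                        class = c("iq_degenerate_baseline", "error")))
  }
  stats::setNames(F0, traces$roi_ids)
}

#' Convert raw fluorescence to dF/F0
#'
#' `dff[i, t] = (F[i, t] - F0[i]) / F0[i]`, with F0 from
#' [compute_baseline()] unless supplied.
#'
#' @param traces A `FluorescenceTraceSet`.
#' @param F0 Optional numeric vector of per-ROI baselines (`> 0`); computed
#'   with `window_s` if missing.
#' @param window_s Baseline window in seconds, forwarded to
#'   [compute_baseline()].
#' @return A `DffTraceSet`: list with `dff` matrix `[roi x frame]`, `F0`,
#'   `window_s`, `sampling_rate`, `roi_ids` and the labels of `traces`.
#' @export
compute_dff <- function(traces, F0 = NULL, window_s = 60) {
  stopifnot(inherits(traces, "FluorescenceTraceSet"))
  if (is.null(F0)) {
    F0 <- compute_baseline(traces, window_s)
  } else {
    if (length(F0) != nrow(traces$F)) stop_invalid("F0 length != number of ROIs")
    if (any(!is.finite(F0)) || any(F0 <= 0)) {
      stop(errorCondition("non-positive baseline F0",
                          class = c("iq_degenerate_baseline", "error")))
    }
  }
  dff <- sweep(sweep(traces$F, 1L, F0, "-"), 1L, F0, "/")
  structure(
    list(dff = dff, F0 = F0, window_s = window_s,
         sampling_rate = traces$sampling_rate, roi_ids = traces$roi_ids,
         group_label = traces$group_label,
         timepoint_label = traces$timepoint_label),
    class = "DffTraceSet")
}
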