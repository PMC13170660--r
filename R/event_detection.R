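## Template-matching detection of calcium transients and per-neuron spike
## rates (spikes/min).

#' Build a library of calcium waveform templates
#'
#' One template per (rise, decay) pair of the full grid, each a
#' difference-of-exponentials sampled at the trace sampling rate and
#' peak-normalised to 1.
#'
#' @param rise_taus,decay_taus Time constants in seconds; every decay must
#'   exceed every rise.
#' @param sampling_rate Hz; must equal the sampling rate of the traces the
#'   library is applied to.
#' @param template_len_s Template length in seconds (default 3).
#' @return A `TemplateLibrary`: list with `templates` (matrix
#'   `[frame x template]`, each column peak 1), `rise_taus`, `decay_taus`
#'   (per template), `template_len` (frames), `sampling_rate`.
#' @export
#' @examples
#' lib <- build_template_library(c(0.05, 0.1), c(0.3, 0.6, 1.2), 8)
#' ncol(lib$templates)  # 6
build_template_library <- function(rise_taus = c(0.05, 0.1, 0.2),
                                   decay_taus = c(0.3, 0.6, 1.2),
                                   sampling_rate = 8, template_len_s = 3) {
  if (any(rise_taus <= 0) || any(decay_taus <= 0)) {
    stop_invalid("time constants must be > 0")
  }
  grid <- expand.grid(rise = rise_taus, decay = decay_taus)
  bad <- grid$decay <= grid$rise
  if (any(bad)) {
    stop_invalid("decay_tau must exceed rise_tau for every template (",
                 sum(bad), " invalid pairs)")
  }
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_number(template_len_s, "template_len_s", lower = 0, strict_lower = TRUE)
  len <- floor(template_len_s * sampling_rate)
  if (len < 3L) stop_invalid("template too short at this sampling rate")
  t <- (seq_len(len) - 1L) / sampling_rate
  templates <- vapply(seq_len(nrow(grid)), function(i) {
    w <- exp(-t / grid$decay[i]) - exp(-t / grid$rise[i])
    w / max(w)
  }, numeric(len))
  structure(
    list(templates = templates, rise_taus = grid$rise,
         decay_taus = grid$decay, template_len = len,
         sampling_rate = sampling_rate),
    class = "TemplateLibrary")
}

#' Detect calcium transients by template matching
#'
#' A window of template length slides across each dF/F0 trace; the
#' similarity of every window to every template is the Pearson correlation
#' between the (mean-subtracted) window and template. Frames where the best
#' similarity reaches `similarity_threshold` and the window's peak dF/F0
#' reaches `min_amplitude` are candidate events; overlapping candidates are
#' resolved by greedy non-maximum suppression on similarity with a
#' refractory window of half the template length (ties broken by earlier
#' onset). Windows must fit entirely inside the trace.
#'
#' @param dff A `DffTraceSet` from [compute_dff()].
#' @param library A `TemplateLibrary`; its sampling rate must match the
#'   traces.
#' @param similarity_threshold Minimum Pearson similarity in `[-1, 1]`
#'   (default 0.75).
#' @param min_amplitude Minimum peak dF/F0 within the matched window
#'   (default 0.01).
#' @return Data frame of events sorted by ROI and onset: `roi_id`,
#'   `onset_frame`, `peak_frame` (1-based), `onset_s`, `peak_s`,
#'   `amplitude` (peak dF/F0), `similarity`, `template_index`.
#' @export
detect_events <- function(dff, library, similarity_threshold = 0.75,
                          min_amplitude = 0.01) {
  stopifnot(inherits(dff, "DffTraceSet"), inherits(library, "TemplateLibrary"))
  check_number(similarity_threshold, "similarity_threshold", lower = -1,
               upper = 1)
  check_number(min_amplitude, "min_amplitude", lower = 0)
  if (abs(library$sampling_rate - dff$sampling_rate) > 1e-9) {
    stop_invalid("template library sampling rate (", library$sampling_rate,
                 " Hz) != trace sampling rate (", dff$sampling_rate, " Hz)")
  }
  L <- library$template_len
  n_frames <- ncol(dff$dff)
  if (L > n_frames) stop_invalid("template longer than trace")
  refractory <- floor(L / 2)
  # centred, unit-norm templates for one-pass correlation
  tc <- sweep(library$templates, 2L, colMeans(library$templates), "-")
  tc <- sweep(tc, 2L, sqrt(colSums(tc^2)), "/")
  n_win <- n_frames - L + 1L
  idx <- outer(0:(L - 1L), seq_len(n_win), "+") + 0L   # L x n_win frame index
  out <- vector("list", nrow(dff$dff))
  for (i in seq_len(nrow(dff$dff))) {
    x <- dff$dff[i, ]
    W <- matrix(x[idx], nrow = L)
    Wc <- sweep(W, 2L, colMeans(W), "-")
    wnorm <- sqrt(colSums(Wc^2))
    sim <- crossprod(Wc, tc) / pmax(wnorm, .Machine$double.eps)  # n_win x n_templates
    sim[wnorm == 0, ] <- -Inf
    best_sim <- apply(sim, 1L, max)
    best_tpl <- max.col(sim, ties.method = "first")
    peak_rel <- apply(W, 2L, which.max)
    peak_amp <- W[cbind(peak_rel, seq_len(n_win))]
    cand <- which(best_sim >= similarity_threshold & peak_amp >= min_amplitude)
    if (length(cand) == 0L) next
    # greedy non-maximum suppression on similarity, ties -> earlier onset
    ord <- cand[order(-best_sim[cand], cand)]
    kept <- integer(0)
    for (j in ord) {
      if (all(abs(j - kept) >= refractory)) kept <- c(kept, j)
    }
    kept <- sort(kept)
    out[[i]] <- data.frame(
      roi_id = dff$roi_ids[i],
      onset_frame = kept,
      peak_frame = kept + peak_rel[kept] - 1L,
      amplitude = peak_amp[kept],
      similarity = best_sim[kept],
      template_index = best_tpl[kept],
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  events <- if (length(out)) {
    do.call(rbind, c(out, make.row.names = FALSE))
  } else {
    data.frame(roi_id = character(), onset_frame = integer(),
               peak_frame = integer(), amplitude = numeric(),
               similarity = numeric(), template_index = integer(),
               stringsAsFactors = FALSE)
  }
  events$onset_s <- (events$onset_frame - 1L) / dff$sampling_rate
  events$peak_s <- (events$peak_frame - 1L) / dff$sampling_rate
  events[, c("roi_id", "onset_frame", "peak_frame", "onset_s", "peak_s",
             "amplitude", "similarity", "template_index")]
}

#' Per-neuron spike rates in spikes/min
#'
#' Counts detected events per ROI and converts to spikes/min; ROIs without
#' events are included with rate 0.
#'
#' @param events Event data frame from [detect_events()].
#' @param duration Recording duration in seconds (`> 0`).
#' @param roi_ids All ROI identifiers to report (so silent ROIs appear).
#' @param group_label,timepoint_label Optional labels attached to every row.
#' @return A `SpikeRateTable` data frame: `roi_id`, `n_events`, `rate`
#'   (spikes/min), `duration_s`, `group`, `timepoint`.
#' @export
spike_rates <- function(events, duration, roi_ids,
                        group_label = NA_character_,
                        timepoint_label = NA_character_) {
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  counts <- table(factor(events$roi_id, levels = roi_ids))
  res <- data.frame(
    roi_id = roi_ids,
    n_events = as.integer(counts),
    rate = as.integer(counts) / (duration / 60),
    duration_s = duration,
    group = group_label,
    timepoint = timepoint_label,
    stringsAsFactors = FALSE)
  class(res) <- c("SpikeRateTable", "data.frame")
  res
}
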