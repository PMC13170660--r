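## Control-referenced hyperactivity thresholds and silent/active/hyperactive
## classification. The threshold is mean + 2 * sample SD of the control
## group's spikes/min, recomputed independently per timepoint.

#' Hyperactivity threshold from control spike rates
#'
#' @param control_rates Numeric vector of control-group spike rates
#'   (spikes/min); at least 2 values.
#' @param timepoint_label Timepoint the threshold belongs to; thresholds are
#'   computed per timepoint and a classification checks the labels match.
#' @return An `ActivityThreshold`: list with `control_mean`, `control_sd`
#'   (sample SD, n-1 denominator), `threshold = mean + 2 * sd`, `n_control`,
#'   `timepoint_label`.
#' @export
#' @examples
#' control_threshold(c(0, 2), "60min")$threshold  # 1 + 2*sqrt(2)
control_threshold <- function(control_rates, timepoint_label = NA_character_) {
  if (!is.numeric(control_rates) || length(control_rates) < 2L) {
    stop(errorCondition("need at least 2 control rates",
                        class = c("iq_insufficient_control", "error")))
  }
  if (any(!is.finite(control_rates)) || any(control_rates < 0)) {
    stop_invalid("control rates must be finite and >= 0")
  }
  m <- mean(control_rates)
  s <- stats::sd(control_rates)
  thr <- m + 2 * s
  if (thr == 0) {
    warning("all-zero control rates give threshold 0; ",
            "any spiking neuron will be called hyperactive",
            call. = FALSE)
  }
  structure(
    list(control_mean = m, control_sd = s, threshold = thr,
         n_control = length(control_rates),
         timepoint_label = timepoint_label),
    class = "ActivityThreshold")
}

#' Classify neurons as silent, active or hyperactive
#'
#' Silent: rate 0. Hyperactive: rate strictly greater than the control
#' threshold (a rate exactly at the threshold is active). Active: anything
#' in between. Classes are exhaustive and mutually exclusive.
#'
#' @param rates A `SpikeRateTable` (or data frame with `roi_id` and `rate`).
#' @param threshold An `ActivityThreshold`; if both carry a non-missing
#'   timepoint label the labels must agree.
#' @return Data frame: `roi_id`, `rate`, `class` (factor
#'   silent/active/hyperactive), `threshold`, `timepoint`.
#' @export
classify_neurons <- function(rates, threshold) {
  stopifnot(inherits(threshold, "ActivityThreshold"))
  if (!all(c("roi_id", "rate") %in% names(rates))) {
    stop_invalid("rates must have roi_id and rate columns")
  }
  tp_rates <- if ("timepoint" %in% names(rates)) unique(rates$timepoint) else NA
  if (!is.na(threshold$timepoint_label) && length(tp_rates) == 1L &&
      !is.na(tp_rates) && tp_rates != threshold$timepoint_label) {
    stop(errorCondition(
      sprintf("rate table timepoint '%s' does not match threshold timepoint '%s'",
              tp_rates, threshold$timepoint_label),
      class = c("iq_label_mismatch", "error")))
  }
  cls <- ifelse(rates$rate == 0, "silent",
                ifelse(rates$rate > threshold$threshold, "hyperactive",
                       "active"))
  data.frame(
    roi_id = rates$roi_id,
    rate = rates$rate,
    class = factor(cls, levels = c("silent", "active", "hyperactive")),
    threshold = threshold$threshold,
    timepoint = threshold$timepoint_label,
    stringsAsFactors = FALSE)
}

#' Fractions of silent, active and hyperactive neurons
#'
#' Counts are taken exactly (integer arithmetic) before the division, so
#' the three fractions always sum to 1.
#'
#' @param classification Data frame from [classify_neurons()] (or any with a
#'   `class` column using the silent/active/hyperactive levels).
#' @return Named numeric vector `(silent, active, hyperactive)`.
#' @export
class_fractions <- function(classification) {
  cls <- classification$class
  if (length(cls) == 0L) stop_invalid("no classified neurons")
  counts <- table(factor(cls, levels = c("silent", "active", "hyperactive")))
  n <- sum(counts)
  stats::setNames(as.numeric(counts) / n, names(counts))
}

#' Normalise group mean rates to a reference group and timepoint
#'
#' Each group's mean spikes/min (per timepoint) divided by the reference
#' group's mean at the reference timepoint — the convention used to report
#' treatment effects relative to untreated cultures.
#'
#' @param rates Data frame with `group`, `timepoint`, `rate` columns
#'   (per-neuron rows, e.g. stacked `SpikeRateTable`s).
#' @param reference_group,reference_timepoint Labels selecting the reference
#'   cell; its mean must be positive.
#' @return Data frame: `group`, `timepoint`, `n`, `mean_rate`,
#'   `normalized_rate`.
#' @export
normalize_rates <- function(rates, reference_group, reference_timepoint) {
  if (!all(c("group", "timepoint", "rate") %in% names(rates))) {
    stop_invalid("rates must have group, timepoint and rate columns")
  }
  agg <- stats::aggregate(rate ~ group + timepoint, data = rates,
                          FUN = mean)
  nn <- stats::aggregate(rate ~ group + timepoint, data = rates,
                         FUN = length)
  ref <- agg$rate[agg$group == reference_group &
                    agg$timepoint == reference_timepoint]
  if (length(ref) != 1L) {
    stop_invalid("reference group/timepoint not found in rates")
  }
  if (ref <= 0) {
    stop(errorCondition("reference group mean rate is 0",
                        class = c("iq_degenerate_reference", "error")))
  }
  data.frame(group = agg$group, timepoint = agg$timepoint,
             n = nn$rate, mean_rate = agg$rate,
             normalized_rate = agg$rate / ref,
             stringsAsFactors = FALSE)
}
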