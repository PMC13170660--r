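# Independent oracles and fixture helpers, deliberately kept separate from
# the implementation paths they check.

# brute-force baseline oracle: tile into windows, linear-interpolation 50th
# percentile per window, mean of window percentiles
oracle_baseline <- function(x, fs, window_s = 60) {
  wf <- floor(window_s * fs)
  starts <- seq(1, length(x), by = wf)
  wins <- lapply(starts, function(s) s:min(s + wf - 1, length(x)))
  last <- wins[[length(wins)]]
  if (length(wins) > 1 && length(last) < wf / 2) {
    wins[[length(wins) - 1]] <- c(wins[[length(wins) - 1]], last)
    wins[[length(wins)]] <- NULL
  }
  mean(vapply(wins, function(ix) unname(quantile(x[ix], 0.5, type = 7)),
              numeric(1)))
}

# enforce a minimum inter-event gap on a spike train (evaluation regime for
# detection benchmarks: transients separated by at least one template length)
thin_gaps <- function(times, gap) {
  keep <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last >= gap) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep
}

# greedy matching of detected onsets to true spike times within a tolerance;
# returns true/false positive/negative counts
match_detections <- function(true_times, detected_onsets, tol_s = 0.5) {
  used <- rep(FALSE, length(detected_onsets))
  tp <- 0L
  for (t in true_times) {
    j <- which(!used & abs(detected_onsets - t) <= tol_s)
    if (length(j)) {
      used[j[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = sum(!used), fn = length(true_times) - tp)
}

# detection benchmark on synthetic traces: spike trains with a minimum gap,
# rendered and pushed through dF/F0 + template matching
detection_benchmark <- function(n_neurons, rate_hz, amplitude, noise_sd,
                                seed, duration = 180, fs = 8, gap = 3) {
  st <- simulate_spike_trains(rep(rate_hz, n_neurons), duration - gap, seed)
  st$spike_times <- lapply(st$spike_times, thin_gaps, gap = gap)
  st$duration <- duration
  tr <- render_fluorescence(st, indicator_kernel(amplitude = amplitude,
                                                 sampling_rate = fs),
                            noise_sd = noise_sd, sampling_rate = fs,
                            seed = seed + 1)
  ev <- detect_events(compute_dff(tr), build_template_library(sampling_rate = fs))
  counts <- rowSums(vapply(seq_len(n_neurons), function(i) {
    match_detections(st$spike_times[[i]],
                     ev$onset_s[ev$roi_id == st$neuron_id[i]])
  }, numeric(3)))
  list(recall = unname(counts["tp"] / max(counts["tp"] + counts["fn"], 1)),
       precision = unname(counts["tp"] / max(counts["tp"] + counts["fp"], 1)),
       fp = counts[["fp"]], n_true = counts[["tp"]] + counts[["fn"]])
}

# hyperactive fractions for one null / effect draw: per-neuron rates from a
# truncated Gaussian (spikes/min), control thresholds applied to both groups
gaussian_rate_fractions <- function(n, mean_spm, sd_spm, multiplier, seed) {
  withr::with_seed(seed, {
    ctrl <- pmax(rnorm(n, mean_spm, sd_spm), 0)
    trt <- pmax(rnorm(n, mean_spm, sd_spm), 0) * multiplier
    thr <- control_threshold(ctrl, "t0")
    list(
      control = class_fractions(classify_neurons(
        data.frame(roi_id = seq_len(n), rate = ctrl), thr)),
      treated = class_fractions(classify_neurons(
        data.frame(roi_id = seq_len(n), rate = trt), thr)))
  })
}
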