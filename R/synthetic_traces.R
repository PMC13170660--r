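## Synthetic calcium traces: Poisson spike trains rendered through a
## GCaMP6f-like indicator kernel, with additive Gaussian noise and optional
## photobleaching. All generators are pure functions of (parameters, seed).

#' Simulate homogeneous Poisson spike trains
#'
#' One spike train per neuron, each a homogeneous Poisson process with the
#' given rate, as the ground-truth model of spontaneous activity underlying
#' the synthetic recordings.
#'
#' @param rates Numeric vector of true rates, events/second, one per neuron
#'   (all `>= 0`).
#' @param duration Recording duration in seconds (`> 0`).
#' @param seed Integer seed; identical seed gives identical spike times.
#' @return A `SpikeTrainSet`: list with `spike_times` (list of sorted numeric
#'   vectors, seconds in `[0, duration)`), `duration`, `true_rate`
#'   (events/s), and `neuron_id`.
#' @export
#' @examples
#' st <- simulate_spike_trains(rates = c(0.05, 0.1), duration = 180, seed = 1)
#' lengths(st$spike_times)
simulate_spike_trains <- function(rates, duration, seed) {
  if (!is.numeric(rates) || length(rates) < 1L || any(!is.finite(rates)) ||
      any(rates < 0)) {
    stop_invalid("rates must be finite and >= 0")
  }
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(seed, "seed")
  spike_times <- withr::with_seed(as.integer(seed), {
    lapply(rates, function(r) {
      n <- stats::rpois(1L, r * duration)
      sort(stats::runif(n, 0, duration))
    })
  })
  structure(
    list(neuron_id = sprintf("n%03d", seq_along(rates)),
         spike_times = spike_times,
         duration = duration,
         true_rate = rates),
    class = "SpikeTrainSet")
}

#' Calcium indicator response kernel
#'
#' Difference-of-exponentials waveform
#' `w(t) = exp(-t/decay_tau) - exp(-t/rise_tau)`, peak-normalised and scaled
#' by `amplitude`. Defaults approximate GCaMP6f kinetics for a single action
#' potential.
#'
#' @param rise_tau,decay_tau Rise and decay time constants in seconds;
#'   `decay_tau > rise_tau > 0`.
#' @param amplitude Peak response in dF/F0 units.
#' @param sampling_rate Sampling rate in Hz at which the kernel is rendered.
#' @return An `IndicatorKernel` object.
#' @export
indicator_kernel <- function(rise_tau = 0.1, decay_tau = 0.6, amplitude = 1,
                             sampling_rate = 8) {
  check_number(rise_tau, "rise_tau", lower = 0, strict_lower = TRUE)
  check_number(decay_tau, "decay_tau", lower = 0, strict_lower = TRUE)
  if (decay_tau <= rise_tau) {
    stop_invalid("decay_tau (", decay_tau, ") must be > rise_tau (",
                 rise_tau, ")")
  }
  check_number(amplitude, "amplitude", lower = 0, strict_lower = TRUE)
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  structure(
    list(rise_tau = rise_tau, decay_tau = decay_tau, amplitude = amplitude,
         sampling_rate = sampling_rate),
    class = "IndicatorKernel")
}

# sample the kernel on the acquisition grid starting at lag 0; peak of the
# sampled waveform equals `amplitude` exactly (normalised after sampling)
render_kernel <- function(kernel, length_s = NULL) {
  stopifnot(inherits(kernel, "IndicatorKernel"))
  if (is.null(length_s)) {
    length_s <- kernel$rise_tau + 7 * kernel$decay_tau
  }
  fs <- kernel$sampling_rate
  n <- max(2L, floor(length_s * fs))
  t <- (seq_len(n) - 1L) / fs
  w <- exp(-t / kernel$decay_tau) - exp(-t / kernel$rise_tau)
  w / max(w) * kernel$amplitude
}

#' Render fluorescence traces from spike trains
#'
#' Converts ground-truth spike trains into raw fluorescence,
#' `F(t) = baseline_F * exp(-bleach_rate * t) * (1 + sum of kernel responses)
#' + Gaussian noise`. Spikes are binned onto the acquisition grid and the
#' kernel responses of overlapping events superpose linearly.
#'
#' @param spikes A `SpikeTrainSet` from [simulate_spike_trains()].
#' @param kernel An `IndicatorKernel`; its `amplitude` is the dF/F0 peak of a
#'   single event.
#' @param baseline_F Baseline fluorescence, arbitrary units (`> 0`).
#' @param noise_sd Additive Gaussian noise SD on F, same units as
#'   `baseline_F`.
#' @param bleach_rate Photobleaching rate, fraction/second (0 disables).
#' @param sampling_rate Acquisition rate in Hz; frame count is
#'   `floor(duration * sampling_rate)`.
#' @param seed Integer seed for the noise draws (ignored when `noise_sd` is
#'   0).
#' @return A `FluorescenceTraceSet`; see [fluorescence_trace_set()].
#' @export
render_fluorescence <- function(spikes, kernel = indicator_kernel(),
                                baseline_F = 100, noise_sd = 0,
                                bleach_rate = 0,
                                sampling_rate = kernel$sampling_rate,
                                seed = 0) {
  stopifnot(inherits(spikes, "SpikeTrainSet"))
  check_number(baseline_F, "baseline_F", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(bleach_rate, "bleach_rate", lower = 0)
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  n_frames <- floor(spikes$duration * sampling_rate)
  if (n_frames < 2L) stop_invalid("recording too short for sampling_rate")
  kern <- indicator_kernel(kernel$rise_tau, kernel$decay_tau,
                           kernel$amplitude, sampling_rate)
  w <- render_kernel(kern)
  tvec <- (seq_len(n_frames) - 1L) / sampling_rate
  decay_env <- exp(-bleach_rate * tvec)
  n_roi <- length(spikes$spike_times)
  F <- matrix(0, nrow = n_roi, ncol = n_frames)
  for (i in seq_len(n_roi)) {
    counts <- tabulate(floor(spikes$spike_times[[i]] * sampling_rate) + 1L,
                       nbins = n_frames)
    resp <- if (any(counts > 0)) {
      stats::convolve(counts, rev(w), type = "open")[seq_len(n_frames)]
    } else {
      numeric(n_frames)
    }
    F[i, ] <- baseline_F * decay_env * (1 + resp)
  }
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed),
                              matrix(stats::rnorm(n_roi * n_frames,
                                                  sd = noise_sd),
                                     nrow = n_roi))
    F <- F + noise
  }
  fluorescence_trace_set(F, sampling_rate, roi_ids = spikes$neuron_id)
}

#' Design of a synthetic neuron population experiment
#'
#' Describes groups of neurons (e.g. a control-IgG group and an
#' autoantibody-treated group) recorded at one or more timepoints. Each
#' neuron has a base rate drawn from a log-normal distribution around the
#' group mean (mean-one multiplicative heterogeneity with coefficient of
#' variation `rate_cv`); a treatment effect multiplies the rate at a given
#' timepoint.
#'
#' @param groups List of group descriptions; each a list with `label`,
#'   `n_neurons`, `rate_mean` (spikes/min), optional `rate_cv` (default
#'   0.6), and `effect_multiplier` — numeric vector, one value per timepoint
#'   (recycled if length 1).
#' @param timepoints Character vector of timepoint labels.
#' @param duration Recording duration per timepoint, seconds.
#' @param sampling_rate Hz.
#' @param kernel An `IndicatorKernel` used when rendering traces.
#' @param baseline_F,noise_sd,bleach_rate Rendering parameters, see
#'   [render_fluorescence()].
#' @param seed Master seed; all per-neuron and per-trace seeds derive from
#'   it.
#' @return A `PopulationDesign` object.
#' @export
population_design <- function(groups = list(
                                list(label = "pCtrl", n_neurons = 300,
                                     rate_mean = 2, effect_multiplier = 1),
                                list(label = "treated", n_neurons = 300,
                                     rate_mean = 2, effect_multiplier = 1)),
                              timepoints = c("0min", "60min"),
                              duration = 180, sampling_rate = 8,
                              kernel = indicator_kernel(amplitude = 0.2),
                              baseline_F = 100, noise_sd = 2,
                              bleach_rate = 0, seed = 1) {
  if (!is.list(groups) || length(groups) < 1L) {
    stop_invalid("groups must be a non-empty list")
  }
  groups <- lapply(groups, function(g) {
    if (is.null(g$label) || is.null(g$n_neurons) || is.null(g$rate_mean)) {
      stop_invalid("each group needs label, n_neurons and rate_mean")
    }
    check_number(g$n_neurons, "n_neurons", lower = 1)
    check_number(g$rate_mean, "rate_mean", lower = 0)
    if (is.null(g$rate_cv)) g$rate_cv <- 0.6
    check_number(g$rate_cv, "rate_cv", lower = 0)
    if (is.null(g$effect_multiplier)) g$effect_multiplier <- 1
    if (any(g$effect_multiplier < 0)) {
      stop_invalid("effect_multiplier must be >= 0")
    }
    g$effect_multiplier <- rep_len(g$effect_multiplier, length(timepoints))
    g
  })
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  structure(
    list(groups = groups, timepoints = timepoints, duration = duration,
         sampling_rate = sampling_rate, kernel = kernel,
         baseline_F = baseline_F, noise_sd = noise_sd,
         bleach_rate = bleach_rate, seed = as.integer(seed)),
    class = "PopulationDesign")
}

#' Simulate a population calcium-imaging experiment
#'
#' Draws per-neuron base rates, applies the per-timepoint effect
#' multipliers, simulates Poisson spike trains, and (optionally) renders raw
#' fluorescence for every group x timepoint. The returned truth table is
#' the ground truth against which detection and classification are
#' validated.
#'
#' @param design A `PopulationDesign` from [population_design()].
#' @param render If `FALSE`, only spike trains and the truth table are
#'   produced (classification-level studies do not need rendered
#'   fluorescence).
#' @return List with `truth` (data.frame: `neuron_id`, `group`, `timepoint`,
#'   `base_rate_spm`, `true_rate_spm`, `design_mean_spm`, `n_spikes`,
#'   `realized_spm`), `spikes` (list of `SpikeTrainSet` keyed
#'   "group.timepoint"), and `traces` (same keys, `FluorescenceTraceSet`,
#'   only when `render = TRUE`).
#' @export
simulate_population <- function(design, render = TRUE) {
  stopifnot(inherits(design, "PopulationDesign"))
  check_flag(render, "render")
  n_groups <- length(design$groups)
  n_tp <- length(design$timepoints)
  seeds <- derive_seeds(design$seed, n_groups * (1L + 2L * n_tp))
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }
  truth <- list()
  spikes <- list()
  traces <- list()
  for (g in design$groups) {
    # mean-one log-normal heterogeneity across neurons
    sdlog <- sqrt(log(1 + g$rate_cv^2))
    base <- withr::with_seed(next_seed(),
                             g$rate_mean * stats::rlnorm(g$n_neurons,
                                                         -sdlog^2 / 2, sdlog))
    for (k in seq_len(n_tp)) {
      tp <- design$timepoints[k]
      mult <- g$effect_multiplier[k]
      rate_spm <- base * mult                     # spikes/min
      st <- simulate_spike_trains(rate_spm / 60, design$duration, next_seed())
      st$neuron_id <- sprintf("%s_%s", g$label, st$neuron_id)
      key <- paste(g$label, tp, sep = ".")
      spikes[[key]] <- st
      if (render) {
        traces[[key]] <- render_fluorescence(
          st, kernel = design$kernel, baseline_F = design$baseline_F,
          noise_sd = design$noise_sd, bleach_rate = design$bleach_rate,
          sampling_rate = design$sampling_rate, seed = next_seed())
        traces[[key]]$group_label <- g$label
        traces[[key]]$timepoint_label <- tp
      } else {
        next_seed()                               # keep stream alignment
      }
      truth[[key]] <- data.frame(
        neuron_id = st$neuron_id,
        group = g$label,
        timepoint = tp,
        base_rate_spm = base,
        true_rate_spm = rate_spm,
        design_mean_spm = g$rate_mean * mult,
        n_spikes = lengths(st$spike_times),
        realized_spm = lengths(st$spike_times) / (design$duration / 60),
        stringsAsFactors = FALSE)
    }
  }
  out <- list(truth = do.call(rbind, c(truth, make.row.names = FALSE)),
              spikes = spikes)
  if (render) out$traces <- traces
  out
}
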