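# Spike-train simulation and fluorescence rendering.

test_that("Poisson spike trains match their rate and respect the contract", {
  # zero rate: empty train
  st0 <- simulate_spike_trains(0, 180, seed = 1)
  expect_length(st0$spike_times[[1]], 0)

  # Monte-Carlo check of the Poisson mean: 1000 neurons at 2 events/s for
  # 180 s; mean count within 3 standard errors of 360
  st <- simulate_spike_trains(rep(2, 1000), 180, seed = 7)
  counts <- lengths(st$spike_times)
  se <- sqrt(2 * 180 / 1000)
  expect_lt(abs(mean(counts) - 360), 3 * se)

  # spike times sorted, in [0, duration)
  expect_true(all(vapply(st$spike_times, function(t) {
    !is.unsorted(t) && all(t >= 0) && all(t < 180)
  }, logical(1))))

  # determinism: same seed, bitwise-identical times
  st2 <- simulate_spike_trains(rep(2, 1000), 180, seed = 7)
  expect_identical(st$spike_times, st2$spike_times)

  expect_error(simulate_spike_trains(-1, 180, 1), class = "iq_invalid_parameter")
  expect_error(simulate_spike_trains(1, -5, 1), class = "iq_invalid_parameter")
})

test_that("fluorescence rendering is exact for closed-form cases", {
  # no spikes, no noise, no bleach: constant trace at baseline
  st <- simulate_spike_trains(0, 180, seed = 1)
  tr <- render_fluorescence(st, baseline_F = 100)
  expect_equal(unname(tr$F[1, ]), rep(100, ncol(tr$F)))

  # one spike: max - baseline = amplitude * baseline (grid-aligned kernel)
  st$spike_times[[1]] <- 30
  tr1 <- render_fluorescence(st, indicator_kernel(amplitude = 0.5))
  expect_equal(max(tr1$F) - 100, 0.5 * 100, tolerance = 1e-12)

  # two coincident spikes: peak response doubles (linear superposition)
  st$spike_times[[1]] <- c(30, 30)
  tr2 <- render_fluorescence(st, indicator_kernel(amplitude = 0.5))
  expect_equal(max(tr2$F) - 100, 2 * (max(tr1$F) - 100), tolerance = 1e-12)

  expect_error(render_fluorescence(st, sampling_rate = 0),
               class = "iq_invalid_parameter")
})

test_that("rendering is linear in the spike trains", {
  kern <- indicator_kernel(amplitude = 0.3)
  mk <- function(times) {
    st <- simulate_spike_trains(0, 60, seed = 1)
    st$spike_times[[1]] <- times
    render_fluorescence(st, kern, baseline_F = 50)$F[1, ]
  }
  a <- mk(c(5, 20))
  b <- mk(c(11, 40))
  ab <- mk(c(5, 11, 20, 40))
  # responses (F/baseline - 1) superpose additively
  expect_equal(ab / 50 - 1, (a / 50 - 1) + (b / 50 - 1), tolerance = 1e-12)
})

test_that("bleaching multiplies the trace by a decaying exponential", {
  st <- simulate_spike_trains(0, 100, seed = 2)
  tr <- render_fluorescence(st, baseline_F = 200, bleach_rate = 0.002)
  t <- (seq_len(ncol(tr$F)) - 1) / 8
  expect_equal(unname(tr$F[1, ]), 200 * exp(-0.002 * t), tolerance = 1e-12)
})

test_that("population simulation carries ground truth and scales effects", {
  des <- population_design(
    groups = list(
      list(label = "pCtrl", n_neurons = 40, rate_mean = 2,
           effect_multiplier = 1),
      list(label = "treated", n_neurons = 40, rate_mean = 2,
           effect_multiplier = c(1, 3))),
    timepoints = c("0min", "60min"), seed = 5)
  pop <- simulate_population(des, render = FALSE)

  # bookkeeping: every neuron has a group label and a true rate
  expect_equal(nrow(pop$truth), 160)
  expect_true(all(!is.na(pop$truth$group)))
  expect_true(all(is.finite(pop$truth$true_rate_spm)))

  # effect multiplier 3: treated design mean is exactly 3x control at 60min
  dm <- unique(pop$truth[pop$truth$timepoint == "60min",
                         c("group", "design_mean_spm")])
  expect_identical(dm$design_mean_spm[dm$group == "treated"],
                   3 * dm$design_mean_spm[dm$group == "pCtrl"])
  # and each neuron's true rate is its base rate times the multiplier
  trt <- pop$truth[pop$truth$group == "treated" &
                     pop$truth$timepoint == "60min", ]
  expect_equal(trt$true_rate_spm, 3 * trt$base_rate_spm, tolerance = 1e-12)

  # determinism of the full population under the master seed
  pop2 <- simulate_population(des, render = FALSE)
  expect_identical(pop$truth, pop2$truth)

  expect_error(population_design(groups = list()),
               class = "iq_invalid_parameter")
})

test_that("null populations are statistically indistinguishable", {
  # effect multiplier 1 for both groups: Wilcoxon test on realized rates is
  # not rejected at alpha = 0.01 in the median over 20 seeds
  p_values <- vapply(1:20, function(s) {
    des <- population_design(
      groups = list(
        list(label = "a", n_neurons = 60, rate_mean = 2),
        list(label = "b", n_neurons = 60, rate_mean = 2)),
      timepoints = "t0", seed = s)
    pop <- simulate_population(des, render = FALSE)
    stats::wilcox.test(realized_spm ~ group, data = pop$truth,
                       exact = FALSE)$p.value
  }, numeric(1))
  expect_gt(median(p_values), 0.01)
})
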