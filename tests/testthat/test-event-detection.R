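# Template library and transient detection.

test_that("template library is a peak-normalised (rise, decay) grid", {
  lib <- build_template_library(c(0.05, 0.1), c(0.3, 0.6, 1.2), 8)
  expect_equal(ncol(lib$templates), 6)
  expect_equal(apply(lib$templates, 2, max), rep(1, 6))
  lib1 <- build_template_library(0.1, 1.0, 8)
  expect_equal(max(lib1$templates), 1)
  expect_error(build_template_library(0.1, 0.05, 8),
               class = "iq_invalid_parameter")
})

test_that("flat traces yield no events and short traces are rejected", {
  flat <- compute_dff(fluorescence_trace_set(matrix(100, 2, 1440), 8))
  lib <- build_template_library(sampling_rate = 8)
  expect_equal(nrow(detect_events(flat, lib)), 0)
  tiny <- structure(list(dff = matrix(0, 1, 10), F0 = 100, window_s = 60,
                         sampling_rate = 8, roi_ids = "r1"),
                    class = "DffTraceSet")
  expect_error(detect_events(tiny, lib), class = "iq_invalid_parameter")
})

test_that("injected transients are recovered with onset accuracy", {
  st <- simulate_spike_trains(0, 180, seed = 1)
  st$spike_times[[1]] <- 10
  tr <- render_fluorescence(st, indicator_kernel(amplitude = 0.5))
  ev <- detect_events(compute_dff(tr), build_template_library(sampling_rate = 8))
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$onset_frame - (10 * 8 + 1)), 2)
  expect_equal(ev$amplitude, 0.5, tolerance = 0.01)

  # an event below the minimum amplitude is rejected
  st$spike_times[[1]] <- 10
  tr_small <- render_fluorescence(st, indicator_kernel(amplitude = 0.005))
  ev_small <- detect_events(compute_dff(tr_small),
                            build_template_library(sampling_rate = 8))
  expect_equal(nrow(ev_small), 0)
})

test_that("noiseless sparse transients give perfect recall and no false positives", {
  bench <- detection_benchmark(n_neurons = 20, rate_hz = 0.04,
                               amplitude = 0.1, noise_sd = 0, seed = 21)
  expect_gt(bench$n_true, 50)
  expect_equal(bench$recall, 1)
  expect_equal(bench$fp, 0)
})

test_that("detection is robust at realistic noise", {
  bench <- detection_benchmark(n_neurons = 100, rate_hz = 0.04,
                               amplitude = 0.2, noise_sd = 2, seed = 33)
  expect_gte(bench$recall, 0.9)
  expect_gte(bench$precision, 0.9)
})

test_that("detected rates increase with the true spike rate", {
  # rates 0.5/1/2/4 events per 10 s
  mean_rates <- vapply(c(0.05, 0.1, 0.2, 0.4), function(r) {
    st <- simulate_spike_trains(rep(r, 10), 180, seed = 55)
    tr <- render_fluorescence(st, indicator_kernel(amplitude = 0.3),
                              noise_sd = 1, seed = 56)
    ev <- detect_events(compute_dff(tr),
                        build_template_library(sampling_rate = 8))
    mean(spike_rates(ev, 180, st$neuron_id)$rate)
  }, numeric(1))
  expect_true(all(diff(mean_rates) >= 0))
})

test_that("raising the similarity threshold never adds events", {
  st <- simulate_spike_trains(rep(0.05, 5), 180, seed = 77)
  tr <- render_fluorescence(st, indicator_kernel(amplitude = 0.2),
                            noise_sd = 2, seed = 78)
  d <- compute_dff(tr)
  lib <- build_template_library(sampling_rate = 8)
  n_events <- vapply(c(0.5, 0.75, 0.9, 0.99),
                     function(s) nrow(detect_events(d, lib, s)), numeric(1))
  expect_true(all(diff(n_events) <= 0))
})

test_that("spike rates are per-minute counts including silent ROIs", {
  ev <- data.frame(roi_id = c("a", "a", "a", "a", "a", "a", "c"))
  rt <- spike_rates(ev, 180, c("a", "b", "c"))
  expect_equal(rt$rate, c(2, 0, 60 * 1 / 180))
  expect_equal(rt$n_events, c(6L, 0L, 1L))
  rt60 <- spike_rates(data.frame(roi_id = rep("a", 12)), 60, "a")
  expect_equal(rt60$rate, 12)
  expect_error(spike_rates(ev, 0, "a"), class = "iq_invalid_parameter")
})
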