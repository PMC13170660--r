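# Control-referenced thresholds, silent/active/hyperactive calls, fractions.

test_that("threshold is mean + 2 sample SD of the control group", {
  thr <- control_threshold(c(1, 1, 1, 1), "t0")
  expect_equal(thr$threshold, 1)
  expect_equal(thr$control_sd, 0)

  thr2 <- control_threshold(c(0, 2), "t0")
  expect_equal(thr2$threshold, 1 + 2 * sqrt(2))  # sample SD, n-1 denominator

  expect_error(control_threshold(numeric(0)),
               class = "iq_insufficient_control")
  expect_error(control_threshold(5), class = "iq_insufficient_control")
  expect_warning(control_threshold(c(0, 0, 0), "t0"), "threshold 0")
})

test_that("classification is exhaustive with a strict hyperactivity cut", {
  thr <- control_threshold(c(1, 2, 3), "t0")
  eps <- 1e-9
  rates <- data.frame(roi_id = c("r1", "r2", "r3", "r4"),
                      rate = c(0, thr$threshold, thr$threshold + eps, 1),
                      timepoint = "t0")
  cls <- classify_neurons(rates, thr)
  expect_equal(as.character(cls$class),
               c("silent", "active", "hyperactive", "active"))
  # classes exhaustive and mutually exclusive by construction
  expect_false(any(is.na(cls$class)))

  # timepoint mismatch is an error
  rates$timepoint <- "t1"
  expect_error(classify_neurons(rates, thr), class = "iq_label_mismatch")
})

test_that("class fractions count exactly and sum to one", {
  cls <- data.frame(class = factor(
    c("silent", "active", "hyperactive", "active"),
    levels = c("silent", "active", "hyperactive")))
  fr <- class_fractions(cls)
  expect_identical(unname(fr), c(0.25, 0.5, 0.25))
  expect_identical(sum(fr), 1)

  all_silent <- data.frame(class = factor(rep("silent", 5),
                                          levels = levels(cls$class)))
  expect_identical(unname(class_fractions(all_silent)), c(1, 0, 0))
  expect_error(class_fractions(data.frame(class = factor(character()))),
               class = "iq_invalid_parameter")

  # invariant to ordering
  withr::with_seed(4, {
    shuffled <- cls[sample(nrow(cls)), , drop = FALSE]
    expect_identical(class_fractions(shuffled), fr)
  })
})

test_that("rate normalisation divides by the reference group mean", {
  rates <- data.frame(
    group = rep(c("NT", "treated"), each = 2),
    timepoint = "60min",
    rate = c(2, 2, 2, 4))
  norm <- normalize_rates(rates, "NT", "60min")
  expect_equal(norm$normalized_rate[norm$group == "NT"], 1)
  expect_equal(norm$normalized_rate[norm$group == "treated"], 1.5)

  zero <- data.frame(group = "NT", timepoint = "t0", rate = c(0, 0))
  expect_error(normalize_rates(zero, "NT", "t0"),
               class = "iq_degenerate_reference")
})

test_that("null calibration: hyperactive tail near the 2-sigma rate", {
  # treated drawn from the same Gaussian as control, n = 300/group: the
  # median hyperactive fraction over seeds sits in [0.5%, 6%] (one-sided
  # 2-sigma tail ~2.3% plus sampling error)
  fracs <- vapply(1:200, function(s) {
    gaussian_rate_fractions(300, 2, 0.5, 1, s)$treated[["hyperactive"]]
  }, numeric(1))
  med <- median(fracs)
  expect_gte(med, 0.005)
  expect_lte(med, 0.06)
})

test_that("self-classification stays below a 10% hyperactive fraction", {
  for (s in 1:20) {
    fr <- gaussian_rate_fractions(300, 2, 0.5, 1, s)$control
    expect_lte(fr[["hyperactive"]], 0.10)
  }
})

test_that("a 3x rate effect raises the hyperactive fraction almost surely", {
  wins <- vapply(1:100, function(s) {
    fr <- gaussian_rate_fractions(300, 2, 0.5, 3, s)
    fr$treated[["hyperactive"]] > fr$control[["hyperactive"]]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
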