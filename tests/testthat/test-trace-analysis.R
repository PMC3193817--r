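# hand-built traces for the extraction primitives
square_trace <- function(level = -100, t_on = 1, t_off = 2, dt = 0.001,
                         total = 3) {
  t <- seq(0, total, by = dt)
  structure(list(time = t, value = ifelse(t >= t_on & t < t_off, level, 0),
                 states = NULL, metadata = list(units = "pA")),
            class = "current_trace")
}

test_that("peak and baseline extraction handles inward deflections and flat traces", {
  pk <- peak_and_baseline(square_trace(-100), c(1, 2))
  expect_equal(pk$baseline, 0)
  expect_equal(pk$peak_amplitude, 100)
  expect_equal(pk$peak_sign, -1)
  expect_false(pk$no_response)

  flat <- peak_and_baseline(square_trace(0), c(1, 2))
  expect_equal(flat$peak_amplitude, 0)
  expect_true(flat$no_response)

  expect_error(peak_and_baseline(square_trace(-100), c(5, 6)),
               "no samples")
})

test_that("peak on a simulated trace equals the open-state maximum", {
  tr <- simulate_trace(fx_control, fx_quick_pulse())
  pk <- peak_and_baseline(tr, c(0.5, 2.5))
  expect_equal(pk$peak_amplitude, max(tr$states[, "A3Ro"]),
               tolerance = 1e-12)
})

test_that("10-90% rise time matches the monoexponential closed form", {
  tau <- 0.010
  t <- seq(0, 0.2, by = 1e-4)
  tr <- structure(list(time = t, value = 1 - exp(-t / tau)),
                  class = "current_trace")
  rt <- rise_time_10_90(tr, baseline = 0, peak_amplitude = 1)
  expect_equal(rt$rise_time, tau * log(9), tolerance = 1e-3)
  expect_false(rt$resolution_limited)

  step <- square_trace(-50, t_on = 1, t_off = 2)
  pk <- peak_and_baseline(step, c(1, 2))
  rt2 <- rise_time_10_90(step, pk$baseline, pk$peak_amplitude, pk$peak_sign,
                         onset_window = c(0.9, 1.5))
  expect_true(rt2$resolution_limited)
  expect_lte(rt2$rise_time, 2 * 0.001)

  expect_error(rise_time_10_90(square_trace(0), 0, 1), "no onset")
})

test_that("rise time on a simulated trace is stable under 10x grid refinement", {
  coarse <- simulate_trace(fx_control, fx_quick_pulse(dt = 0.002))
  fine <- simulate_trace(fx_control, fx_quick_pulse(dt = 0.0002))
  rt <- function(tr) {
    pk <- peak_and_baseline(tr, c(0.5, 2.5))
    rise_time_10_90(tr, pk$baseline, pk$peak_amplitude, pk$peak_sign,
                    onset_window = c(0.5, pk$peak_time))$rise_time
  }
  expect_lt(abs(rt(coarse) - rt(fine)), 0.002)
})

test_that("biexponential fitting recovers noiseless parameters to < 0.1%", {
  t <- seq(0, 2, by = 0.001)
  cases <- list(c(Af = 0.6, tf = 0.04, As = 0.4, ts = 0.8, C = 0),
                c(Af = 0.6, tf = 0.04, As = 0.4, ts = 0.8, C = 0.05),
                c(Af = 200, tf = 0.1, As = 100, ts = 1.2, C = 10))
  for (p in cases) {
    y <- p[["Af"]] * exp(-t / p[["tf"]]) +
      p[["As"]] * exp(-t / p[["ts"]]) + p[["C"]]
    tr <- structure(list(time = t, value = y), class = "current_trace")
    fit <- fit_biexponential(tr, c(0, 2))
    got <- c(fit$amp_fast, fit$tau_fast, fit$amp_slow, fit$tau_slow)
    expect_lt(max(abs(got - p[1:4]) / p[1:4]), 1e-3)
    expect_false(fit$monoexponential)
    expect_gt(fit$fit_r2, 0.999999)
  }
})

test_that("monoexponential decay raises the degeneracy flag", {
  t <- seq(0, 2, by = 0.001)
  tr <- structure(list(time = t, value = exp(-t / 0.3)),
                  class = "current_trace")
  fit <- fit_biexponential(tr, c(0, 2))
  expect_true(fit$monoexponential)
  expect_error(fit_biexponential(tr, c(0, 0.01)), "20 samples")
})

test_that("tau_slow stays accurate under 2% recording noise", {
  t <- seq(0, 2, by = 0.001)
  clean <- 0.6 * exp(-t / 0.04) + 0.4 * exp(-t / 0.8)
  set.seed(7)
  errs <- replicate(25, {
    tr <- structure(list(time = t,
                         value = clean + stats::rnorm(length(t), 0, 0.02)),
                    class = "current_trace")
    abs(fit_biexponential(tr, c(0, 2))$tau_slow - 0.8) / 0.8
  })
  expect_lt(stats::median(errs), 0.05)
})

test_that("recovery ratio and current density follow their definitions", {
  expect_equal(recovery_ratio(100, 24), 24)
  expect_equal(recovery_ratio(50, 50), 100)
  over <- recovery_ratio(100, 120)
  expect_equal(as.numeric(over), 120)
  expect_true(attr(over, "over_100"))
  expect_error(recovery_ratio(0, 10), "positive")

  expect_equal(current_density(338, 28.9), 338 / 28.9)  # ~11.7 pA/pF
  expect_equal(current_density(0, 15), 0)
  expect_equal(current_density(100, 10), 10)
  expect_error(current_density(100, 0), "capacitance")
})

test_that("recovery from the trace analysis equals the simulator's own readout", {
  pp <- simulate_paired_pulse(fx_control, sampling_interval = 0.002)
  expect_identical(recovery_ratio(pp$first_peak, pp$second_peak),
                   pp$recovery_percent)
})

test_that("feature extraction is stable under 2x resampling", {
  f1 <- analyze_trace(simulate_trace(fx_control, fx_quick_pulse(dt = 0.002)))
  f2 <- analyze_trace(simulate_trace(fx_control, fx_quick_pulse(dt = 0.001)))
  expect_equal(f1$peak_amplitude, f2$peak_amplitude, tolerance = 1e-3)
  expect_equal(f1$rise_time_10_90, f2$rise_time_10_90, tolerance = 0.05)
  expect_equal(f1$tau_fast, f2$tau_fast, tolerance = 0.02)
  expect_equal(f1$tau_slow, f2$tau_slow, tolerance = 0.05)
})

test_that("group comparison reports means, SEM and two-sided p-values", {
  g <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  same <- compare_groups(g, g, method = "ranksum")
  expect_gt(same$p_value, 0.99)
  expect_equal(same$mean_a, same$mean_b)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")

  # separation of 6 SEM units is detected essentially always
  set.seed(11)
  n <- 30; sdv <- 1
  hits <- replicate(200, {
    a <- stats::rnorm(n, 0, sdv)
    b <- stats::rnorm(n, 6 * sdv / sqrt(n), sdv)
    compare_groups(a, b, method = "ttest")$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})
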