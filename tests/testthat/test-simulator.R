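test_that("no agonist means no activation", {
  tr <- simulate_trace(fx_control,
                       pulse_protocol(10, 0, sampling_interval = 0.01))
  expect_lt(max(tr$value), 1e-6)
})

test_that("ODE solution agrees with the matrix-exponential oracle on both rate sets", {
  prot <- paired_pulse_protocol(0.01, 2, 30, sampling_interval = 0.002)
  for (rs in list(fx_control, fx_mbcd)) {
    ode <- simulate_trace(rs, prot)
    ora <- propagate_expm(rs, prot)
    expect_lt(max(abs(ode$states - ora$states)), 1e-6)
  }
})

test_that("propagation conserves total occupancy and stays non-negative over 60 s", {
  prot <- pulse_protocol(c(2, 58), c(0.01, 0), sampling_interval = 0.005)
  tr <- simulate_trace(fx_control, prot)
  expect_lt(max(abs(rowSums(tr$states) - 1)), 1e-9)
  expect_gt(min(tr$states), -1e-9)
})

test_that("the expm propagator is stationary at the zero-agonist steady state", {
  ss0 <- steady_state(fx_scheme, fx_control, 0)
  tr <- propagate_expm(fx_control,
                       pulse_protocol(1, 0, sampling_interval = 0.1),
                       init = ss0)
  drift <- abs(tr$states[nrow(tr$states), ] - as.numeric(ss0))
  expect_lt(max(drift), 1e-12)
})

test_that("paired-pulse recovery grows with the inter-pulse interval", {
  recov <- vapply(c(5, 10, 30, 60, 120), function(iv) {
    simulate_paired_pulse(fx_control, interval = iv,
                          sampling_interval = 0.002)$recovery_percent
  }, numeric(1))
  expect_true(all(diff(recov) > 0))
})

test_that("recovery approaches 100% for very long intervals", {
  pp <- simulate_paired_pulse(fx_control, interval = 1e4,
                              sampling_interval = 0.01)
  expect_equal(pp$recovery_percent, 100, tolerance = 0.01)
})

test_that("peak open-state occupancy increases with the gating rate k4", {
  peaks <- vapply(c(10, 40, 75, 110, 150), function(k4) {
    rs <- update_rates(fx_control, k4 = k4)
    max(simulate_trace(rs, fx_quick_pulse())$value)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("faster open-to-desensitized transition (d5) accelerates decay", {
  half_time <- function(d5) {
    tr <- simulate_trace(update_rates(fx_control, d5 = d5), fx_quick_pulse())
    v <- tr$value
    ipk <- which.max(v)
    tr$time[ipk - 1 + which(v[ipk:length(v)] <= v[ipk] / 2)[1]] - tr$time[ipk]
  }
  expect_lt(half_time(13), half_time(9))
})

test_that("reported peaks are insensitive to solver-tolerance halving", {
  prot <- fx_quick_pulse()
  p1 <- max(simulate_trace(fx_control, prot)$value)
  p2 <- max(simulate_trace(fx_control, prot,
                           rtol = 5e-9, atol = 5e-11)$value)
  expect_lt(abs(p1 - p2), 1e-6)
})

test_that("protocol construction rejects degenerate input", {
  expect_error(pulse_protocol(c(1, 0), c(0.01, 0)), "positive")
  expect_error(pulse_protocol(1, -0.01), "non-negative")
  expect_error(pulse_protocol(1e5, 0, sampling_interval = 0.001,
                              max_samples = 1e6), "max_samples")
  expect_error(paired_pulse_protocol(pulse_duration = 2, interval = 1),
               "interval")
})
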