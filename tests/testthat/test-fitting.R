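make_spec <- function(free, start, targets, ...) {
  fit_spec(free, fx_control, targets,
           lower = setNames(start / 2, free),
           upper = setNames(start * 2, free), ...)
}

test_that("objective is zero at the generating rates and positive away from them", {
  targets <- simulated_features(fx_control, sampling_interval = 0.002)
  truth <- c(k4 = 75, d5 = 9, n4 = 0.44)
  spec <- make_spec(names(truth), truth, targets)
  expect_lt(objective_loss(truth, spec), 1e-6)
  expect_gt(objective_loss(c(k4 = 37.5, d5 = 9, n4 = 0.44), spec), 1e-3)
})

test_that("objective scales linearly with a common weight factor", {
  targets <- simulated_features(fx_control, sampling_interval = 0.002)
  cand <- c(k4 = 60, d5 = 11, n4 = 0.5)
  w1 <- setNames(rep(1, length(targets)), names(targets))
  s1 <- make_spec(names(cand), cand, targets, weights = w1)
  s3 <- make_spec(names(cand), cand, targets, weights = 3 * w1)
  expect_equal(objective_loss(cand, s3), 3 * objective_loss(cand, s1),
               tolerance = 1e-10)
})

test_that("fit specification validates bounds and weights", {
  targets <- c(peak = 0.5)
  expect_error(fit_spec("q9", fx_control, targets,
                        lower = c(q9 = 1), upper = c(q9 = 2)), "canonical")
  expect_error(fit_spec("k4", fx_control, targets,
                        lower = c(k4 = -1), upper = c(k4 = 2)), "bounds")
  expect_error(fit_spec("k4", fx_control, targets,
                        lower = c(k4 = 1), upper = c(k4 = Inf)), "bounds")
  expect_error(fit_spec("k4", fx_control, targets,
                        lower = c(k4 = 1), upper = c(k4 = 2),
                        weights = c(peak = 0)), "weights")
  expect_warning(fit_spec(names(fx_control)[1:7], fx_control, targets,
                          lower = setNames(rep(1, 7), names(fx_control)[1:7]),
                          upper = setNames(rep(2, 7), names(fx_control)[1:7])),
                 "identifiability")
})

test_that("fitting is deterministic for a fixed seed and recovers a single free constant", {
  targets <- simulated_features(fx_control, sampling_interval = 0.002)
  spec <- make_spec("k4", c(k4 = 55), targets, seed = 3,
                    max_eval = 40, n_starts = 1)
  r1 <- fit_rates(spec)
  r2 <- fit_rates(spec)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$loss, r2$loss)
  expect_lt(abs(r1$par[["k4"]] - 75) / 75, 0.05)
})

test_that("unreachable targets are flagged as not converged", {
  targets <- simulated_features(fx_control, sampling_interval = 0.002)
  targets[["peak"]] <- 10  # occupancy cannot exceed 1
  spec <- make_spec("k4", c(k4 = 75), targets, max_eval = 25, n_starts = 1)
  res <- fit_rates(spec)
  expect_false(res$converged)
})

test_that("the condition diff isolates the six constants that move", {
  d <- mbcd_delta_report(fx_control, fx_mbcd)
  expect_setequal(d$rate, c("k4", "d5", "n4", "n1", "n2", "n3"))
  expect_equal(d$direction[d$rate == "k4"], "decrease")
  expect_equal(d$value_a[d$rate == "k4"], 75)
  expect_equal(d$value_b[d$rate == "k4"], 40)
  expect_equal(d$value_b[d$rate == "n3"], 0.057)
  expect_true(all(d$direction[d$rate != "k4"] == "increase"))
  expect_equal(nrow(mbcd_delta_report(fx_control, fx_control)), 0)
})
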