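test_that("canonical scheme has the expected topology", {
  expect_length(fx_scheme$states, 10)
  expect_equal(nrow(fx_scheme$transitions), 26)
  tx <- fx_scheme$transitions
  # 13 reversible pairs: every edge has its reverse
  expect_true(all(paste(tx$to, tx$from) %in% paste(tx$from, tx$to)))
  expect_setequal(tx$rate, c(paste0("k", 1:4), paste0("l", 1:4),
                             paste0("m", 1:4), paste0("n", 1:4),
                             paste0("d", 1:5), paste0("r", 1:5)))
  # concentration enters only through the six binding steps
  expect_setequal(tx$rate[tx$ligand_order == 1],
                  c("k1", "k2", "k3", "m1", "m2", "m3"))
  # wiring fixed by the receptor's described operation
  expect_equal(tx$to[tx$rate == "d5"], "A3Df")
  expect_equal(tx$from[tx$rate == "d5"], "A3Ro")
  expect_equal(tx$to[tx$rate == "n4"], "A3D")
  expect_equal(tx$from[tx$rate == "n4"], "A3Df")
  expect_equal(tx$to[tx$rate == "k4"], "A3Ro")
})

test_that("scheme validation rejects malformed schemes", {
  broken <- fx_scheme
  broken$transitions <- broken$transitions[-1, ]  # drop R -> AR
  expect_error(validate_scheme(broken, strict = TRUE), "26 transitions")
  isolated <- fx_scheme
  isolated$states <- c(isolated$states, "X")
  expect_error(validate_scheme(isolated), "incoming")
  relabeled <- fx_scheme
  relabeled$transitions$ligand_order[relabeled$transitions$rate == "k4"] <- 1L
  expect_error(validate_scheme(relabeled, strict = TRUE), "ligand_order")
})

test_that("scheme serialization round-trips losslessly", {
  path <- tempfile(fileext = ".json")
  write_scheme(fx_scheme, path)
  back <- read_scheme(path, strict = TRUE)
  expect_identical(back$states, fx_scheme$states)
  expect_identical(back$transitions, fx_scheme$transitions)
})

test_that("packaged rate sets carry the published values", {
  expect_equal(fx_control[["k1"]], 24000)
  expect_equal(fx_control[["k4"]], 75)
  expect_equal(fx_control[["d5"]], 9.0)
  expect_equal(fx_control[["n4"]], 0.44)
  expect_equal(unname(as.numeric(fx_control[c("n1", "n2", "n3")])),
               c(0.01, 0.02, 0.03))
  expect_equal(fx_mbcd[["k4"]], 40)
  expect_equal(fx_mbcd[["d5"]], 13.0)
  expect_equal(fx_mbcd[["n4"]], 0.68)
  expect_equal(unname(as.numeric(fx_mbcd[c("n1", "n2", "n3")])),
               c(0.019, 0.038, 0.057))
  # binding steps in mM^-1 s^-1, everything else s^-1
  u <- attr(fx_control, "units")
  expect_setequal(names(u)[u == "mM^-1 s^-1"],
                  c("k1", "k2", "k3", "m1", "m2", "m3"))
})

test_that("rate-set validation names the offending constant", {
  expect_error(load_rate_set(fx_rate_file(drop = "r5")), "r5")
  expect_error(load_rate_set(fx_rate_file(set = list(k2 = -1))), "k2")
  vals <- setNames(as.numeric(fx_control), names(fx_control))
  expect_error(rate_set(c(vals, bogus = 1)), "bogus")
  expect_error(rate_set(vals, units = c(k1 = "s^-1")), "unit mismatch")
  expect_error(load_rate_set("no_such_condition"), "not found")
})

test_that("generator follows mass action and conserves occupancy", {
  Q <- build_generator(fx_scheme, fx_control, 0.01)
  expect_equal(Q["AR", "R"], 24000 * 0.01)
  expect_equal(Q["A3Ro", "A3R"], 75)       # gating is concentration-free
  expect_lt(max(abs(colSums(Q))), 1e-12)
  for (conc in c(0, 0.001, 0.1, 1)) {
    for (rs in list(fx_control, fx_mbcd)) {
      expect_lt(max(abs(colSums(build_generator(fx_scheme, rs, conc)))),
                1e-12)
    }
  }
  Q0 <- build_generator(fx_scheme, fx_control, 0)
  expect_equal(Q0["AR", "R"], 0)
  expect_equal(Q0["AD", "D"], 0)
  expect_error(build_generator(fx_scheme, fx_control, -0.01),
               "non-negative")
})

test_that("steady state solves Qv = 0 and matches the two-state balance at zero agonist", {
  ss0 <- steady_state(fx_scheme, fx_control, 0)
  expect_equal(sum(ss0), 1, tolerance = 1e-12)
  expect_true(all(ss0 >= 0))
  d1 <- fx_control[["d1"]]; r1 <- fx_control[["r1"]]
  expect_equal(ss0[["D"]], d1 / (d1 + r1), tolerance = 1e-6)
  expect_gt(ss0[["R"]], 0.999)

  # at 0.01 mM the steady state is the long-time limit of propagation
  ss <- steady_state(fx_scheme, fx_control, 0.01)
  expect_equal(sum(ss), 1, tolerance = 1e-12)
  long <- propagate_expm(fx_control,
                         pulse_protocol(1e4, 0.01, sampling_interval = 1e3))
  final <- long$states[nrow(long$states), ]
  expect_lt(max(abs(final - as.numeric(ss))), 1e-8)
})
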