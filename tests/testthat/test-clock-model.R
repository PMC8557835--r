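test_that("Bmal1 transcription multiplier has the documented limits", {
  th <- default_clock_params()
  base <- c(pREV = 0, pROR = 0, pCB = 1, pPC = 1)
  expect_equal(transcription_rate("Bmal1", base, th), 1)
  # ROR saturation -> fold-transcription ratio g1
  hi_ror <- c(pREV = 0, pROR = 1e8, pCB = 1, pPC = 1)
  expect_equal(transcription_rate("Bmal1", hi_ror, th),
               unclass(th)[["g1"]], tolerance = 1e-6)
  # REV-ERB saturation -> full repression
  hi_rev <- c(pREV = 1e8, pROR = 1, pCB = 1, pPC = 1)
  expect_lt(transcription_rate("Bmal1", hi_rev, th), 1e-6)
  expect_error(transcription_rate("Bmal1", c(pREV = -1, pROR = 0), th),
               "negative")
})

test_that("activated genes respond to CLOCK/BMAL and PER/CRY as described", {
  th <- default_clock_params()
  lo <- transcription_rate("Per2", c(pCB = 0, pPC = 1), th)
  hi <- transcription_rate("Per2", c(pCB = 1e8, pPC = 0), th)
  expect_equal(lo, 1)
  expect_equal(hi, unclass(th)[["f_P"]], tolerance = 1e-6)
  # PER/CRY attenuates the activation
  mid <- transcription_rate("Per2", c(pCB = 1, pPC = 0.5), th)
  inh <- transcription_rate("Per2", c(pCB = 1, pPC = 5), th)
  expect_lt(inh, mid)
  # Cry1 additionally repressed by REV-ERB
  c0 <- transcription_rate("Cry1", c(pCB = 1, pPC = 1, pREV = 0), th)
  c1 <- transcription_rate("Cry1", c(pCB = 1, pPC = 1, pREV = 5), th)
  expect_lt(c1, c0)
})

test_that("zero transcription levels give pure exponential decay", {
  th <- unclass(default_clock_params())
  th[paste0("V_", c("B", "P", "R", "O", "C", "K"))] <- 0
  tr <- simulate_clock(clock_params(th), hours = 48, burn_in_h = 100)
  expect_lt(max(tr$states[nrow(tr$states), ]), 1e-2)
  expect_lt(max(tr$states[nrow(tr$states), 1:6]), 1e-4)
})

test_that("reference clock oscillates in the circadian range", {
  tr <- ref_traj()
  for (v in setdiff(clock_state_names(), "mK")) {
    m <- rhythm_metrics(tr, v)
    expect_true(m$rhythmic, label = paste(v, "rhythmic"))
    expect_gt(m$period, 20)
    expect_lt(m$period, 28)
    expect_gt(m$relamp, 0.05)
  }
})

test_that("compiled and reference R right-hand sides agree", {
  th <- default_clock_params()
  a <- simulate_clock(th, hours = 24, dt = 0.5, burn_in_h = 48)
  b <- simulate_clock(th, hours = 24, dt = 0.5, burn_in_h = 48,
                      engine = "r")
  expect_lt(max(abs(a$states - b$states)), 1e-6)
})

test_that("output grid refinement leaves state values unchanged", {
  th <- default_clock_params()
  a <- simulate_clock(th, hours = 24, dt = 0.5, burn_in_h = 48)
  b <- simulate_clock(th, hours = 24, dt = 0.25, burn_in_h = 48)
  keep <- match(a$time, b$time)
  expect_lt(max(abs(a$states - b$states[keep, ])), 1e-5)
})

test_that("simulation is deterministic given parameters and grid", {
  th <- default_clock_params()
  expect_identical(simulate_clock(th, hours = 12, burn_in_h = 24)$states,
                   simulate_clock(th, hours = 12, burn_in_h = 24)$states)
})

test_that("rhythm metrics recover analytic signal properties", {
  t <- seq(0, 96, by = 0.1)
  mk <- function(x) {
    structure(list(time = t, states = matrix(x, ncol = 1,
                                             dimnames = list(NULL, "v"))),
              class = "clock_trajectory")
  }
  m <- rhythm_metrics(mk(2 + cos(2 * pi * t / 23.5)), "v")
  expect_equal(m$period, 23.5, tolerance = 0.1)
  expect_equal(m$relamp, 1, tolerance = 0.01)   # (max - min) / mean = 2/2

  flat <- rhythm_metrics(mk(rep(3, length(t))), "v")
  expect_false(flat$rhythmic)

  m1 <- rhythm_metrics(mk(2 + cos(2 * pi * t / 24)), "v")
  m2 <- rhythm_metrics(mk(2 + cos(2 * pi * (t - 6) / 24)), "v")
  expect_equal(phase_distance(m1$phase, m2$phase, 24), 6, tolerance = 0.05)
})

test_that("joint Vmax/alpha scaling leaves the limit-cycle mean stable", {
  # report-style robustness check: doubling one gene's production and
  # degradation jointly roughly preserves its circadian mean
  th <- unclass(default_clock_params())
  base <- rhythm_metrics(ref_traj(), "mO")$mean
  th[["V_O"]] <- th[["V_O"]] * 2
  th[["a_O"]] <- th[["a_O"]] * 2
  tr2 <- simulate_clock(clock_params(th), hours = 96, dt = 0.25)
  m2 <- rhythm_metrics(tr2, "mO")$mean
  expect_lt(abs(m2 - base) / base, 0.1)
})

test_that("parameter validation enforces positivity and Hill bounds", {
  th <- unclass(default_clock_params())
  th[["a_B"]] <- -1
  expect_error(clock_params(th), "positive")
  th <- unclass(default_clock_params())
  th[["h_I"]] <- 0.5
  expect_error(clock_params(th), "Hill")
  expect_error(clock_params(unclass(default_clock_params())[-1]), "missing")
})

test_that("clock parameters round-trip through JSON", {
  th <- default_clock_params()
  path <- file.path(tempdir(), "params.json")
  write_clock_params(th, path)
  expect_equal(unclass(read_clock_params(path)), unclass(th),
               tolerance = 1e-12)
  # the shipped reference fixture matches the in-code defaults
  ref <- system.file("extdata", "clock_params_reference.json",
                     package = "circlock")
  expect_equal(unclass(read_clock_params(ref)), unclass(th),
               tolerance = 1e-9)
})
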