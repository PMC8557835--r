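flat_spec <- function(amplitude, noise_sd, step_h = 3, reps = 3) {
  d <- bio_design <- function(...) NULL  # silence lints; use class_spec direct
  mk <- function(acro) list(mesor = 10, amplitude = amplitude,
                            acrophase_h = acro, noise_sd = noise_sd,
                            step_h = step_h, duration_h = 72,
                            replicates = reps, harm2 = c(0, 0),
                            harm3 = c(0, 0))
  class_spec(1, "A", "female",
             list(activity = mk(2), temperature = mk(8), food_intake = mk(14),
                  corticosterone = mk(20), melatonin = mk(5)))
}

test_that("noiseless cosinor biomarkers follow mesor/amplitude/acrophase", {
  sp <- flat_spec(amplitude = 0, noise_sd = 0)
  tab <- generate_biomarkers(sp, seed = 1)
  expect_true(all(tab$value[tab$biomarker != "food_intake"] == 10))

  sp2 <- flat_spec(amplitude = 3, noise_sd = 0)
  tab2 <- generate_biomarkers(sp2, seed = 1)
  # value at the acrophase equals mesor + amplitude
  act <- tab2[tab2$biomarker == "activity" & tab2$time_h == 2, ]
  expect_equal(act$value, rep(13, nrow(act)))
  # cosinor shape everywhere
  tt <- tab2[tab2$biomarker == "temperature", ]
  expect_equal(tt$value, 10 + 3 * cos(2 * pi * (tt$time_h - 8) / 24))
})

test_that("sampling designs give the expected row counts", {
  sp <- flat_spec(amplitude = 2, noise_sd = 0.5)
  tab <- generate_biomarkers(sp, seed = 3)
  # hormone design: duration/3 + 1 distinct times x 3 replicates
  for (b in c("corticosterone", "melatonin")) {
    d <- tab[tab$biomarker == b, ]
    expect_identical(nrow(d), 75L)
    expect_identical(length(unique(d$time_h)), 25L)
  }
})

test_that("food intake is interval consumption of the underlying rate", {
  sp <- flat_spec(amplitude = 0, noise_sd = 0, step_h = 4)
  tab <- generate_biomarkers(sp, seed = 1)
  food <- tab[tab$biomarker == "food_intake", ]
  expect_equal(unique(food$value), 10 * 4)  # constant rate x bin width
  expect_identical(length(unique(food$time_h)), 18L)
})

test_that("same seed reproduces tables bit-identically", {
  sp <- default_class_specs()$class2
  expect_identical(generate_biomarkers(sp, seed = 42),
                   generate_biomarkers(sp, seed = 42))
  th <- default_clock_params()
  expect_identical(generate_invitro_expression(th, 0.1, seed = 9),
                   generate_invitro_expression(th, 0.1, seed = 9))
})

test_that("invalid class specifications are rejected", {
  expect_error(flat_spec(amplitude = -1, noise_sd = 0), "amplitude")
  expect_error(flat_spec(amplitude = 1, noise_sd = -0.1), "noise_sd")
})

test_that("ground truth rejects a regulator paired with its integral", {
  expect_error(ground_truth("Bmal1", "H1",
                            c("activity", "int_activity"), c(1, 1)),
               "integral")
  expect_silent(ground_truth("Bmal1", "H1",
                             c("activity", "int_temperature"), c(1, 1)))
})

test_that("noiseless in vitro output matches the simulator", {
  th <- default_clock_params()
  dat <- generate_invitro_expression(th, noise_sd = 0, seed = 1,
                                     step_h = 2, duration_h = 48)
  tr <- simulate_clock(th, hours = 48, dt = 0.25)
  for (g in c("Bmal1", "Rev-Erba")) {
    d <- dat[dat$gene == g, ]
    sim <- approx(tr$time, tr$states[, circlock:::gene_state(g)],
                  xout = d$time_h)$y
    expect_equal(d$value, sim, tolerance = 1e-6)
  }
  # all six noiseless profiles oscillate with circadian period
  for (g in setdiff(clock_genes(), "Clock")) {
    m <- rhythm_metrics(tr, circlock:::gene_state(g))
    expect_gt(m$period, 20)
    expect_lt(m$period, 28)
  }
})

test_that("zero true weights give the unforced limit cycle plus noise", {
  fx <- study_fixture()
  truth0 <- ground_truth("Bmal1", "H1", c("activity", "food_intake"),
                         beta = c(0, 0), noise_sd = 0)
  out <- generate_invivo_expression(truth0, default_clock_params(),
                                    fx$panels, seed = 5)
  tr <- ref_traj()
  d <- out[out$gene == "Bmal1" & out$class == 1 & out$replicate == 1, ]
  sim <- approx(tr$time, tr$states[, "mB"], xout = d$time_h)$y
  expect_equal(d$value, sim, tolerance = 0.02)
})

test_that("a larger forcing excursion increases the forced gene's amplitude", {
  # the combination sum(beta * z) is standardized before entering the
  # multiplier, so the forcing strength is set by the excursion scale
  fx <- study_fixture()
  amp_of <- function(eps) {
    truth <- ground_truth("Bmal1", "H1", "food_intake", 1, noise_sd = 0)
    out <- generate_invivo_expression(truth, default_clock_params(),
                                      fx$panels, seed = 5, eps_scale = eps)
    d <- out[out$gene == "Bmal1" & out$class == 1 & out$replicate == 1, ]
    diff(range(d$value))
  }
  expect_gt(amp_of(0.3), amp_of(0.15))
})

test_that("non-positive forcing multiplier raises a diagnostic error", {
  fx <- study_fixture()
  truth <- ground_truth("Bmal1", "H1", "food_intake", 1, noise_sd = 0)
  expect_error(generate_invivo_expression(truth, default_clock_params(),
                                          fx$panels, seed = 5,
                                          eps_scale = 2),
               "non-positive")
})
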