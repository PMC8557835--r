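#' Sampling design and cosinor parameters for one mouse class
#'
#' Each of the five biomarkers carries cosinor parameters (mesor, amplitude,
#' acrophase) in its own units, a replicate noise sd, and a sampling design
#' (grid step, duration, replicate count). Food intake is interval
#' consumption: the generated value for a bin starting at `t` is the
#' integral of the underlying cosinor rate over `[t, t + step]`.
#'
#' @param class_id Integer 1-4.
#' @param strain,sex Labels (e.g. "B6D2F1", "female").
#' @param biomarkers Named list (names: the direct features of
#'   [regulator_features()]) of lists with fields `mesor`, `amplitude`,
#'   `acrophase_h`, `noise_sd`, `step_h`, `duration_h`, `replicates`.
#' @return A `class_spec` object.
#' @export
class_spec <- function(class_id, strain, sex, biomarkers) {
  need <- regulator_features()[1:5]
  if (!all(need %in% names(biomarkers))) {
    stop("biomarkers must be given for: ", paste(need, collapse = ", "))
  }
  for (b in need) {
    p <- biomarkers[[b]]
    stopifnot(all(c("mesor", "amplitude", "acrophase_h", "noise_sd",
                    "step_h", "duration_h", "replicates") %in% names(p)))
    if (p$amplitude < 0) stop(b, ": amplitude must be >= 0")
    if (p$noise_sd < 0) stop(b, ": noise_sd must be >= 0")
    if (p$acrophase_h < 0 || p$acrophase_h >= 24) {
      stop(b, ": acrophase_h must lie in [0, 24)")
    }
    if (p$replicates < 1) stop(b, ": replicate count must be >= 1")
  }
  structure(list(class_id = as.integer(class_id), strain = strain, sex = sex,
                 biomarkers = biomarkers), class = "class_spec")
}

bio_design <- function(mesor, amplitude, acrophase_h, noise_sd,
                       step_h, duration_h = 72, replicates,
                       harm2 = c(0, 0), harm3 = c(0, 0)) {
  list(mesor = mesor, amplitude = amplitude, acrophase_h = acrophase_h,
       noise_sd = noise_sd, step_h = step_h, duration_h = duration_h,
       replicates = replicates, harm2 = harm2, harm3 = harm3)
}

# waveform harmonics: each entry c(fraction of fundamental amplitude,
# phase offset in h). Real biomarkers are not sinusoids (activity bouts,
# meal bursts); without harmonic content all ten panel columns would be
# linear combinations of one cosine/sine pair and no specific regulator
# could be identified.
waveform_value <- function(p, t) {
  w <- 2 * pi / 24
  h2 <- p$harm2 %||% c(0, 0); h3 <- p$harm3 %||% c(0, 0)
  p$mesor + p$amplitude * (
    cos(w * (t - p$acrophase_h)) +
      h2[1] * cos(2 * w * (t - p$acrophase_h - h2[2])) +
      h3[1] * cos(3 * w * (t - p$acrophase_h - h3[2])))
}

# integral of the waveform over [t, t + dt] (food-intake bins)
waveform_bin_integral <- function(p, t, dt) {
  w <- 2 * pi / 24
  h2 <- p$harm2 %||% c(0, 0); h3 <- p$harm3 %||% c(0, 0)
  term <- function(k, frac, off) {
    (p$amplitude * frac / (k * w)) *
      (sin(k * w * (t + dt - p$acrophase_h - off)) -
         sin(k * w * (t - p$acrophase_h - off)))
  }
  p$mesor * dt + term(1, 1, 0) + term(2, h2[1], h2[2]) + term(3, h3[1], h3[2])
}

#' Default specifications of the four mouse classes
#'
#' Classes 1/2 are female/male of one strain, 3/4 female/male of another.
#' The defaults encode the qualitative between-class contrasts of the study
#' design: rest-activity differs in mesor and relative amplitude between the
#' sexes while phases match; temperature profiles are near-identical across
#' classes; food-intake rhythms are strong in classes 1-2 and weak in 3-4;
#' corticosterone rhythm is weak in class 2; melatonin (the negative
#' control) is rhythmic everywhere. Sampling designs: activity and
#' temperature every 10 min for 72 h with 8 replicates; hormones every 3 h
#' with 3 replicates; food intake as 4 h interval consumption with 3
#' replicates. Absolute values are placeholders in plausible physiological
#' units, not measurements.
#'
#' @return Named list of four `class_spec` objects.
#' @export
default_class_specs <- function() {
  act <- function(mesor, amp) bio_design(mesor, amp, 16, 6, 1 / 6, 72, 8,
                                         harm2 = c(0.35, 2), harm3 = c(0.15, 1))
  temp <- function(mesor) bio_design(mesor, 0.5, 16, 0.25, 1 / 6, 72, 8,
                                     harm2 = c(0.12, 3), harm3 = c(0.05, 5))
  food <- function(amp) bio_design(0.15, amp, 17, 0.06, 4, 72, 3,
                                   harm2 = c(0.3, 1.5), harm3 = c(0.12, 4))
  cort <- function(amp, noise) bio_design(70, amp, 13, noise, 3, 72, 3,
                                          harm2 = c(0.2, 4), harm3 = c(0.08, 2))
  mel <- function() bio_design(30, 20, 20, 8, 3, 72, 3,
                               harm2 = c(0.15, 5), harm3 = c(0.06, 3))
  mk <- function(id, strain, sex, a_mesor, a_amp, t_mesor, f_amp, c_amp, c_noise) {
    class_spec(id, strain, sex, list(
      activity = act(a_mesor, a_amp),
      temperature = temp(t_mesor),
      food_intake = food(f_amp),
      corticosterone = cort(c_amp, c_noise),
      melatonin = mel()))
  }
  list(
    class1 = mk(1, "B6D2F1", "female", 25, 20, 36.5, 0.12, 50, 20),
    class2 = mk(2, "B6D2F1", "male", 16, 9, 36.45, 0.12, 22, 28),
    class3 = mk(3, "B6CBAF1", "female", 23, 17, 36.55, 0.04, 50, 20),
    class4 = mk(4, "B6CBAF1", "male", 15, 8, 36.5, 0.04, 50, 20))
}

#' Generate raw biomarker tables for one class
#'
#' Values follow `mesor + amplitude * cos(2 pi (t - acrophase) / 24)` plus
#' optional second/third waveform harmonics (scaled by the fundamental
#' amplitude, so a zero-amplitude biomarker stays flat) and Gaussian
#' replicate noise at each design time. Food intake is generated as
#' interval consumption (integral of the underlying rate over each bin).
#' Melatonin is generated like every other biomarker: it is the pipeline's
#' negative control downstream, not omitted here.
#'
#' @param spec A [class_spec()].
#' @param seed Integer seed; same seed, same table.
#' @return Long-format data.frame: `class`, `biomarker`, `time_h`,
#'   `replicate`, `value`.
#' @export
#' @examples
#' tab <- generate_biomarkers(default_class_specs()$class1, seed = 1)
#' table(tab$biomarker)
generate_biomarkers <- function(spec, seed) {
  stopifnot(inherits(spec, "class_spec"))
  set.seed(as.integer(seed))
  out <- lapply(names(spec$biomarkers), function(b) {
    p <- spec$biomarkers[[b]]
    if (b == "food_intake") {
      times <- seq(0, p$duration_h - p$step_h, by = p$step_h)
      base <- waveform_bin_integral(p, times, p$step_h)
    } else {
      times <- seq(0, p$duration_h, by = p$step_h)
      base <- waveform_value(p, times)
    }
    reps <- seq_len(p$replicates)
    d <- expand.grid(time_h = times, replicate = reps)
    d$value <- rep(base, times = length(reps)) +
      stats::rnorm(nrow(d), 0, p$noise_sd)
    data.frame(class = spec$class_id, biomarker = b,
               time_h = d$time_h, replicate = d$replicate, value = d$value)
  })
  do.call(rbind, out)
}

#' Ground-truth regulator model for synthetic in vivo data
#'
#' @param target_gene `"Bmal1"`, `"Per2"` or `"Rev-Erba"`.
#' @param hypothesis `"H1"` (transcription) or `"H2"` (degradation).
#' @param features Feature names or indices into [regulator_features()];
#'   must not contain a regulator together with its integral, and at most 5.
#' @param beta True weights: vector (shared by the four classes) or a
#'   4 x length(features) matrix of per-class weights.
#' @param noise_sd Observation noise sd on generated mRNA.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(target_gene, hypothesis, features, beta,
                         noise_sd = 0) {
  target_gene <- match.arg(target_gene, c("Bmal1", "Per2", "Rev-Erba"))
  hypothesis <- match.arg(hypothesis, c("H1", "H2"))
  if (is.numeric(features)) features <- regulator_features()[features]
  stopifnot(all(features %in% regulator_features()))
  idx <- match(features, regulator_features())
  if (length(idx) > 5) stop("at most 5 features")
  if (anyDuplicated(ifelse(idx > 5, idx - 5, idx))) {
    stop("a regulator and its integral cannot both be in the model")
  }
  if (is.null(dim(beta))) beta <- matrix(beta, 4, length(idx), byrow = TRUE)
  stopifnot(nrow(beta) == 4, ncol(beta) == length(idx), noise_sd >= 0)
  structure(list(target_gene = target_gene, hypothesis = hypothesis,
                 features = features, beta = beta, noise_sd = noise_sd),
            class = "ground_truth")
}

# forcing multiplier on the panel grid for one class:
# f = 1 + eps_scale * standardized(sum_j beta_j z_j); the applied shift and
# scale are recorded as attributes
forcing_from_truth <- function(truth, panel, class_idx, eps_scale) {
  g <- drop(panel$z[, truth$features, drop = FALSE] %*%
              truth$beta[class_idx, ])
  if (sd_pop(g) == 0) {
    # zero (or constant) combination: no rhythmic forcing
    return(structure(rep(1, length(g)), shift = 1, scale = eps_scale,
                     comb_mean = mean(g), comb_sd = 0))
  }
  st <- standardize_vec(g)
  f <- 1 + eps_scale * st$values
  if (any(f <= 0)) {
    stop("forcing multiplier non-positive after shift (min = ",
         signif(min(f), 4), "); reduce eps_scale or the weights")
  }
  structure(f, shift = 1, scale = eps_scale, comb_mean = st$mean,
            comb_sd = st$sd)
}

# periodic steady state of the forced scalar gene ODE driven by the unforced
# modulator trajectory:
#   H1: dx/dt = f(t) V Tr(t) - a x     H2: dx/dt = V Tr(t) - f(t) a x
forced_gene_profile <- function(truth, params, traj, forcing_fun,
                                out_times, burn_cycles = 10) {
  g <- truth$target_gene
  p <- unclass(params)
  V <- p[[paste0("V_", c(Bmal1 = "B", Per2 = "P", `Rev-Erba` = "R")[g])]]
  a <- p[[paste0("a_", c(Bmal1 = "B", Per2 = "P", `Rev-Erba` = "R")[g])]]
  tr_vals <- transcription_rate(g, traj$states, params)
  tr_fun <- periodic_interp(traj$time, tr_vals, period = 24)
  rhs <- function(t, x, parms) {
    f <- forcing_fun(t)
    if (truth$hypothesis == "H1") {
      list(f * V * tr_fun(t) - a * x)
    } else {
      list(V * tr_fun(t) - f * a * x)
    }
  }
  burn <- burn_cycles * 24
  times <- sort(unique(c(seq(0, burn, by = 0.5), burn + out_times)))
  x0 <- traj$states[1, gene_state(g)]
  out <- deSolve::ode(c(x = unname(x0)), times, rhs, NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  out[match(burn + out_times, out[, "time"]), "x"]
}

#' Generate in vivo clock-gene expression under a known regulator model
#'
#' The target gene's ODE is integrated with the forcing
#' `f(t) = 1 + eps_scale * standardized(sum_j beta_j z_j(t))` multiplying its
#' transcription (H1) or degradation (H2) term, while the rest of the clock
#' follows the unforced limit cycle (regulators force the gene; feedback
#' from the gene back to the clock is not rewired, matching the inference
#' model's assumption). Non-target genes are reported from the unforced
#' model. Gaussian observation noise is added.
#'
#' @param truth A [ground_truth()].
#' @param params A [clock_params()] vector.
#' @param panels List of 4 `regulator_panel` objects (classes 1-4).
#' @param seed Integer seed.
#' @param eps_scale Forcing excursion around 1 (default 0.3); the shift (1)
#'   and scale are recorded in the result's `forcing` attribute.
#' @param step_h,duration_h,replicates Sampling design of the output table.
#' @return Long-format data.frame `class`, `gene`, `time_h`, `replicate`,
#'   `value`, with attributes `truth` and `forcing`.
#' @export
generate_invivo_expression <- function(truth, params, panels, seed,
                                       eps_scale = 0.3, step_h = 1,
                                       duration_h = 48, replicates = 3) {
  stopifnot(inherits(truth, "ground_truth"), length(panels) == 4)
  set.seed(as.integer(seed))
  traj <- simulate_clock(params, hours = 48, dt = 0.25)
  times <- seq(0, duration_h, by = step_h)
  genes <- c("Bmal1", "Per2", "Rev-Erba")
  finfo <- vector("list", 4)
  rows <- list()
  for (ci in 1:4) {
    fvec <- forcing_from_truth(truth, panels[[ci]], ci, eps_scale)
    finfo[[ci]] <- attributes(fvec)
    ffun <- periodic_interp(panels[[ci]]$grid, as.numeric(fvec), period = 24)
    xf <- forced_gene_profile(truth, params, traj, ffun, times)
    for (g in genes) {
      base <- if (g == truth$target_gene) {
        xf
      } else {
        stats::approx(traj$time, traj$states[, gene_state(g)], xout = times)$y
      }
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          class = ci, gene = g, time_h = times, replicate = r,
          value = base + stats::rnorm(length(times), 0, truth$noise_sd))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth
  attr(out, "forcing") <- finfo
  out
}

#' Generate in vitro clock-gene expression
#'
#' Unforced limit-cycle mRNA profiles of the six modelled genes, scaled by
#' `obs_scale`, sampled on a regular grid with Gaussian noise.
#'
#' @param params A [clock_params()] vector.
#' @param noise_sd Observation noise sd.
#' @param seed Integer seed.
#' @param step_h,duration_h,replicates Sampling design.
#' @return Long-format data.frame `gene`, `time_h`, `replicate`, `value`.
#' @export
generate_invitro_expression <- function(params, noise_sd = 0, seed = 1,
                                        step_h = 1, duration_h = 48,
                                        replicates = 1) {
  set.seed(as.integer(seed))
  params <- clock_params(params)
  traj <- simulate_clock(params, hours = duration_h, dt = min(step_h, 0.25))
  times <- seq(0, duration_h, by = step_h)
  rows <- lapply(clock_genes(), function(g) {
    base <- stats::approx(traj$time, traj$states[, gene_state(g)],
                          xout = times)$y * unclass(params)[["obs_scale"]]
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      data.frame(gene = g, time_h = times, replicate = r,
                 value = base + stats::rnorm(length(times), 0, noise_sd))
    }))
  })
  do.call(rbind, rows)
}
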