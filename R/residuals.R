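#' Perturbation and acceptance settings for residual-trajectory ensembles
#'
#' Under hypothesis H3 the in vivo parameter vector is a Gaussian
#' perturbation of an in vitro fit: `theta_j_vivo = theta_j_vitro + eps`,
#' `eps ~ N(0, (theta_j * sigma_eff)^2)`, applied to the target gene's
#' kinetic parameters plus the Sobol-selected set. The nominal scaling
#' factor is `sigma = 10`; `sigma_eff` defaults to `1/sigma` (the scale is
#' read as a standard deviation; the literal reading `sd = theta_j * sigma`
#' is available via `sigma_literal = TRUE` and rejects nearly every draw).
#'
#' @param sigma Nominal scaling factor (default 10).
#' @param sigma_eff Effective relative sd (default `1/sigma`).
#' @param sigma_literal Use `sd = theta_j * sigma` verbatim.
#' @param n Target number of accepted trajectories per class (default 2000).
#' @param period_range Accepted period window (h).
#' @param min_relamp Minimum relative amplitude (strict).
#' @param min_phase_gap Minimum antagonist phase separation (h, strict).
#' @param extra_coords Additional perturbed parameter names (typically the
#'   Sobol selection [sobol_select()]).
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(sigma = 10, sigma_eff = 1 / sigma,
                              sigma_literal = FALSE, n = 2000,
                              period_range = c(20, 28), min_relamp = 0.05,
                              min_phase_gap = 6, extra_coords = character(0)) {
  stopifnot(n >= 1, min_relamp > 0, min_phase_gap > 0,
            all(period_range > 0), sigma_eff >= 0)
  structure(list(sigma = sigma,
                 sigma_eff = if (sigma_literal) sigma else sigma_eff,
                 n = n, period_range = period_range,
                 min_relamp = min_relamp, min_phase_gap = min_phase_gap,
                 extra_coords = extra_coords),
            class = "perturbation_spec")
}

# kinetic parameters entering the residual formulas for one gene
gene_kinetic_params <- function(gene) {
  switch(gene,
    Bmal1 = c("V_B", "a_B", "g1", "g2", "g3", "g4", "g5"),
    Per2 = c("V_P", "a_P", "f_P", "k_P", "h_a", "k_I", "h_I"),
    `Rev-Erba` = c("V_R", "a_R", "f_R", "k_R", "h_a", "k_I", "h_I"),
    stop("unsupported gene: ", gene))
}

#' Perturb clock parameters (hypothesis H3)
#'
#' Adds Gaussian noise with sd `theta_j * sigma_eff` to the selected
#' coordinates, resampling each until positive (at most 1000 tries).
#' Consumes the caller's RNG stream.
#'
#' @param params A [clock_params()] vector.
#' @param coords Parameter names to perturb.
#' @param sigma_eff Relative sd.
#' @return Perturbed `clock_params`.
#' @export
perturb_params <- function(params, coords, sigma_eff) {
  th <- unclass(params)
  stopifnot(all(coords %in% names(th)))
  for (j in coords) {
    s <- th[[j]] * sigma_eff
    if (s == 0) next
    for (k in 1:1000) {
      cand <- th[[j]] + stats::rnorm(1, 0, s)
      if (cand > 0 && !(j %in% .hill_coef_names && cand < 1)) break
      cand <- NA
    }
    if (is.na(cand)) stop("could not draw a positive value for ", j)
    th[[j]] <- cand
  }
  clock_params(th)
}

#' Realistic-clock acceptance filter
#'
#' A simulated clock is accepted iff (i) every state variable (except the
#' structurally constitutive Clock mRNA) is rhythmic with period inside
#' `period_range` and relative amplitude strictly above `min_relamp`, and
#' (ii) the circular phase separations between the antagonist pairs
#' REV-ERB / ROR and PER/CRY / CLOCK/BMAL are strictly larger than
#' `min_phase_gap` hours.
#'
#' @param traj A `clock_trajectory` covering at least 2 cycles.
#' @param period_range,min_relamp,min_phase_gap Criteria thresholds.
#' @return Logical with attribute `diagnostics` (per-state metrics and the
#'   two phase gaps).
#' @export
accept_clock <- function(traj, period_range = c(20, 28), min_relamp = 0.05,
                         min_phase_gap = 6) {
  vars <- setdiff(clock_state_names(), "mK")
  ms <- lapply(vars, function(v) rhythm_metrics(traj, v))
  names(ms) <- vars
  periods <- vapply(ms, `[[`, numeric(1), "period")
  relamps <- vapply(ms, `[[`, numeric(1), "relamp")
  rhythmic <- vapply(ms, `[[`, logical(1), "rhythmic")
  ok_states <- all(rhythmic) && !any(is.na(periods)) &&
    all(periods >= period_range[1] & periods <= period_range[2]) &&
    all(relamps > min_relamp)
  gaps <- c(rev_ror = NA_real_, pc_cb = NA_real_)
  if (ok_states) {
    per <- mean(periods)
    gaps["rev_ror"] <- phase_distance(ms$pREV$phase, ms$pROR$phase, per)
    gaps["pc_cb"] <- phase_distance(ms$pPC$phase, ms$pCB$phase, per)
  }
  ok <- isTRUE(ok_states) && all(gaps > min_phase_gap)
  structure(ok, diagnostics = list(periods = periods, relamps = relamps,
                                   gaps = gaps))
}

modulator_matrix <- function(traj, at) {
  sapply(clock_modulators(), function(v) {
    stats::approx(traj$time, traj$states[, v], xout = at)$y
  })
}

#' Residual trajectory under H1 (forcing on transcription)
#'
#' Inverts the gene's ODE for the forcing:
#' `y(t_i) = (dx/dt(t_i) + alpha x(t_i)) / Transc(M(t_i))`, with the
#' derivative as a forward difference on the grid, for `i = 1..N-1`.
#' Basal transcription `Vmax` is absorbed into the regression weights.
#'
#' @param gene `"Bmal1"`, `"Per2"` or `"Rev-Erba"`.
#' @param x_vivo Smoothed gene expression on `grid` (length N).
#' @param traj `clock_trajectory` providing the modulator profiles.
#' @param params The (possibly perturbed) `clock_params` used for `alpha`
#'   and the Hill terms.
#' @param grid Common time grid (h), length N.
#' @param standardize Standardize the result (zero mean, unit population
#'   sd); default TRUE.
#' @return A `residual_trajectory`: numeric vector of length N-1 with
#'   attributes `gene`, `hypothesis`, `grid` and `standardized`.
#' @export
residual_h1 <- function(gene, x_vivo, traj, params, grid,
                        standardize = TRUE) {
  stopifnot(length(x_vivo) == length(grid))
  n <- length(grid)
  i <- seq_len(n - 1)
  M <- modulator_matrix(traj, grid[i])
  tr <- transcription_rate(gene, M, params)
  if (any(tr <= 0)) stop("non-positive transcription multiplier on grid")
  alpha <- unclass(params)[[gene_kinetic_params(gene)[2]]]
  dx <- diff(x_vivo) / diff(grid)
  y <- (dx + alpha * x_vivo[i]) / tr
  finalize_residual(y, gene, "H1", grid[i], standardize)
}

#' Residual trajectory under H2 (forcing on degradation)
#'
#' `y(t_i) = (Vmax Transc(M(t_i)) - dx/dt(t_i)) / x(t_i)`; the degradation
#' rate `alpha` is absorbed into the regression weights. Spikes caused by
#' near-zero expression are preserved (they are diagnostic of this
#' hypothesis).
#'
#' @inheritParams residual_h1
#' @return A `residual_trajectory` of length N-1.
#' @export
residual_h2 <- function(gene, x_vivo, traj, params, grid,
                        standardize = TRUE) {
  stopifnot(length(x_vivo) == length(grid))
  if (any(x_vivo == 0)) stop("zero expression on grid: H2 residual undefined")
  n <- length(grid)
  i <- seq_len(n - 1)
  M <- modulator_matrix(traj, grid[i])
  tr <- transcription_rate(gene, M, params)
  kp <- gene_kinetic_params(gene)
  vmax <- unclass(params)[[kp[1]]]
  dx <- diff(x_vivo) / diff(grid)
  y <- (vmax * tr - dx) / x_vivo[i]
  finalize_residual(y, gene, "H2", grid[i], standardize)
}

finalize_residual <- function(y, gene, hypothesis, grid_i, standardize) {
  if (any(!is.finite(y))) stop("non-finite residual values")
  raw <- y
  if (standardize) y <- standardize_vec(y)$values
  structure(y, gene = gene, hypothesis = hypothesis, grid = grid_i,
            standardized = standardize, raw = raw,
            class = "residual_trajectory")
}

#' Generate an ensemble of residual trajectories
#'
#' Repeats {pick a base parameter set round-robin, perturb (H3), simulate,
#' apply [accept_clock()], invert the ODE for each class} until `n`
#' perturbed clocks are accepted; each accepted clock yields one residual
#' per class.
#'
#' Perturbed clocks are simulated phase-anchored: each starts from its base
#' parameter set's limit-cycle state at data time 0 with no additional
#' burn-in. A perturbed in vivo clock is a perturbation of a clock whose
#' phase was set by the data it was calibrated to; re-converging every
#' perturbed clock from scratch would randomize its phase (a +/-1 h period
#' change becomes an arbitrary phase shift after a long transient) and
#' inject pure phase noise into the inversion.
#'
#' @param gene Target gene.
#' @param hypothesis `"H1"` or `"H2"`.
#' @param x_vivo List of 4 numeric vectors: smoothed expression of `gene`
#'   on `grid`, one per class.
#' @param base_params List of `clock_params` (e.g. the 10 best in vitro
#'   fits); cycled round-robin to spread parameter uncertainty.
#' @param spec A [perturbation_spec()]; `spec$n` trajectories are produced.
#' @param grid Common grid (h).
#' @param seed Integer seed.
#' @param sim_hours,sim_dt Simulation window per attempt.
#' @param max_attempts Abort threshold (default `1e5`); the run also aborts
#'   if the running acceptance rate falls below 0.1% after 1000 attempts.
#' @return A `residual_ensemble`: list with `y` (array n x (N-1) x 4),
#'   `gene`, `hypothesis`, `grid`, `acceptance_rate`, `provenance`
#'   (per-trajectory perturbed parameters and base-set index).
#' @export
generate_ensemble <- function(gene, hypothesis, x_vivo, base_params, spec,
                              grid, seed, sim_hours = 72, sim_dt = 0.5,
                              max_attempts = 1e5) {
  stopifnot(inherits(spec, "perturbation_spec"), length(x_vivo) == 4)
  hypothesis <- match.arg(hypothesis, c("H1", "H2"))
  if (inherits(base_params, "clock_params")) base_params <- list(base_params)
  set.seed(as.integer(seed))
  coords <- unique(c(gene_kinetic_params(gene), spec$extra_coords))
  resid_fun <- if (hypothesis == "H1") residual_h1 else residual_h2
  anchors <- lapply(base_params, function(th) {
    simulate_clock(th, hours = 1, dt = 0.5)$states[1, ]
  })
  n <- spec$n
  y <- array(NA_real_, c(n, length(grid) - 1, 4))
  prov <- vector("list", n)
  accepted <- 0L; attempts <- 0L
  while (accepted < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts ||
        (attempts > 1000 && accepted / attempts < 0.001)) {
      stop("acceptance rate too low (", accepted, "/", attempts,
           "); loosen the perturbation or check the base parameter sets")
    }
    base_idx <- ((attempts - 1L) %% length(base_params)) + 1L
    th <- perturb_params(base_params[[base_idx]], coords, spec$sigma_eff)
    traj <- tryCatch(
      simulate_clock(th, hours = sim_hours, dt = sim_dt, burn_in_h = 0,
                     x0 = anchors[[base_idx]]),
      error = function(e) NULL)
    if (is.null(traj)) next
    if (!isTRUE(accept_clock(traj, spec$period_range, spec$min_relamp,
                             spec$min_phase_gap))) next
    res <- tryCatch(
      lapply(1:4, function(ci) resid_fun(gene, x_vivo[[ci]], traj, th, grid)),
      error = function(e) NULL)
    if (is.null(res)) next  # e.g. non-positive multiplier: counts as rejected
    accepted <- accepted + 1L
    for (ci in 1:4) y[accepted, , ci] <- as.numeric(res[[ci]])
    prov[[accepted]] <- list(params = unclass(th), base_idx = base_idx)
  }
  structure(list(y = y, gene = gene, hypothesis = hypothesis,
                 grid = grid[seq_len(length(grid) - 1)],
                 acceptance_rate = accepted / attempts,
                 provenance = prov),
            class = "residual_ensemble")
}

#' Extract one class's trajectories from an ensemble
#'
#' @param ens A `residual_ensemble`.
#' @param class_idx Class 1-4.
#' @return (N-1) x n matrix (time points by trajectories).
#' @export
ensemble_matrix <- function(ens, class_idx) {
  t(matrix(ens$y[, , class_idx], nrow = dim(ens$y)[1]))
}

#' @export
print.residual_ensemble <- function(x, ...) {
  cat("<residual_ensemble>", x$gene, x$hypothesis, ":", dim(x$y)[1],
      "trajectories x", dim(x$y)[2], "time points x 4 classes;",
      "acceptance rate", signif(x$acceptance_rate, 3), "\n")
  invisible(x)
}

#' Write / read a residual ensemble as tidy CSV
#'
#' Columns `class`, `trajectory_id`, `time_h`, `y`; gene and hypothesis are
#' stored in a JSON sidecar together with the acceptance rate.
#'
#' @param ens A `residual_ensemble`.
#' @param path CSV path.
#' @return `write_ensemble` returns `path` invisibly.
#' @export
write_ensemble <- function(ens, path) {
  n <- dim(ens$y)[1]
  d <- expand.grid(time_i = seq_along(ens$grid), trajectory_id = seq_len(n),
                   class = 1:4)
  d$time_h <- ens$grid[d$time_i]
  d$y <- ens$y[cbind(d$trajectory_id, d$time_i, d$class)]
  utils::write.csv(d[, c("class", "trajectory_id", "time_h", "y")], path,
                   row.names = FALSE)
  jsonlite::write_json(
    list(gene = ens$gene, hypothesis = ens$hypothesis,
         acceptance_rate = ens$acceptance_rate),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
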