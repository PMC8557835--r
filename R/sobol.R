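#' Sobol-based selection of the most influential clock parameters
#'
#' First-order Sobol sensitivity indices (Saltelli sampling, Jansen-style
#' estimator) of the circadian mean, relative amplitude and phase of each
#' modulator species (REV-ERB, ROR, CLOCK/BMAL, PER/CRY), over a
#' `+/- span` hypercube around the reference parameters. For each
#' (modulator, characteristic) pair the top-`p` parameter set is formed;
#' `p` is raised until the intersection across all pairs reaches
#' `target_size` parameters (or the largest `p` keeping it at most
#' `target_size`).
#'
#' @param params A [clock_params()] vector (hypercube centre).
#' @param n_sample Saltelli base sample size (simulation cost is
#'   `n_sample * (k + 2)`).
#' @param span Relative half-width of the hypercube (default 0.5).
#' @param seed Integer seed.
#' @param param_names Parameter universe to rank (default: all).
#' @param modulators,characteristics Output definitions.
#' @param target_size Desired size of the intersection P (default 5).
#' @param sim_hours,sim_dt,burn_in_h Simulation settings per sample.
#' @return List with `P` (selected parameter names), `p` (per-pair depth
#'   used), `indices` (k x 12 matrix of first-order indices), `n_valid`
#'   (usable simulations per output).
#' @export
sobol_select <- function(params, n_sample = 256, span = 0.5, seed = 1,
                         param_names = clock_param_names(),
                         modulators = clock_modulators(),
                         characteristics = c("mean", "relamp", "phase"),
                         target_size = 5, sim_hours = 48, sim_dt = 0.5,
                         burn_in_h = 240) {
  th <- unclass(clock_params(params))
  k <- length(param_names)
  set.seed(as.integer(seed))
  lo <- th[param_names] * (1 - span)
  hi <- th[param_names] * (1 + span)
  lo[intersect(param_names, .hill_coef_names)] <-
    pmax(lo[intersect(param_names, .hill_coef_names)], 1)
  draw <- function() {
    m <- matrix(stats::runif(n_sample * k), n_sample, k)
    sweep(sweep(m, 2, hi - lo, `*`), 2, lo, `+`)
  }
  A <- draw(); B <- draw()
  colnames(A) <- colnames(B) <- param_names

  out_names <- unlist(lapply(modulators, function(m)
    paste(m, characteristics, sep = ".")))
  evaluate <- function(mat) {
    t(apply(mat, 1, function(row) {
      thi <- th; thi[param_names] <- row
      tr <- tryCatch(simulate_clock(clock_params(thi), hours = sim_hours,
                                    dt = sim_dt, burn_in_h = burn_in_h),
                     error = function(e) NULL)
      if (is.null(tr)) return(rep(NA_real_, length(out_names)))
      unlist(lapply(modulators, function(m) {
        mm <- rhythm_metrics(tr, m)
        vapply(characteristics, function(ch) as.numeric(mm[[ch]]), numeric(1))
      }))
    }))
  }
  YA <- evaluate(A); YB <- evaluate(B)
  colnames(YA) <- colnames(YB) <- out_names

  S <- matrix(NA_real_, k, length(out_names),
              dimnames = list(param_names, out_names))
  n_valid <- setNames(numeric(length(out_names)), out_names)
  for (i in seq_len(k)) {
    ABi <- A; ABi[, i] <- B[, i]
    YABi <- evaluate(ABi)
    colnames(YABi) <- out_names
    for (o in out_names) {
      ok <- stats::complete.cases(YA[, o], YB[, o], YABi[, o])
      if (sum(ok) < 8) next
      v <- stats::var(c(YA[ok, o], YB[ok, o]))
      if (v == 0) { S[i, o] <- 0; next }
      S[i, o] <- mean(YB[ok, o] * (YABi[ok, o] - YA[ok, o])) / v
      n_valid[o] <- sum(ok)
    }
  }

  pick <- function(p) {
    Reduce(intersect, lapply(out_names, function(o) {
      names(sort(abs(S[, o]), decreasing = TRUE))[seq_len(p)]
    }))
  }
  P <- character(0); p_used <- NA_integer_
  for (p in seq_len(k)) {
    cand <- pick(p)
    if (length(cand) > target_size) break
    P <- cand; p_used <- p
    if (length(cand) == target_size) break
  }
  if (length(P) < target_size) {
    warning("intersection reached only ", length(P), " parameters (target ",
            target_size, "); returning the best achievable set")
  }
  list(P = P, p = p_used, indices = S, n_valid = n_valid)
}
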