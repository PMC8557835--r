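#' Calibrate the clock model to in vitro expression data
#'
#' Multi-start weighted least squares between the simulated and observed
#' mRNA profiles of the six clock genes. Optimization runs on the log of
#' the selected parameters (bounded), starting from the supplied values and
#' from log-uniform draws around them; per-gene weights equalize the scale
#' of the six genes (inverse observed variance). The `n_best` lowest-cost
#' parameter sets that still satisfy the realistic-clock criteria
#' ([accept_clock()]) are returned.
#'
#' @param data Long-format in vitro table (`gene`, `time_h`, `replicate`,
#'   `value`) as produced by [generate_invitro_expression()].
#' @param init A [clock_params()] vector: optimization centre and the
#'   values of unfitted parameters.
#' @param param_subset Names of the parameters to fit; default the per-gene
#'   transcription levels and degradation rates.
#' @param n_starts Number of optimization starts (>= `n_best`).
#' @param n_best Number of parameter sets to return (default 10).
#' @param spread Multiplicative half-range of the log-uniform start draws.
#' @param seed Integer seed.
#' @param sim_dt Simulation output step during fitting (h).
#' @param maxit Optimizer iteration cap per start.
#' @return List of `n_best` `clock_params`, sorted by cost; costs and
#'   convergence info in attribute `fits`.
#' @export
fit_invitro <- function(data, init = default_clock_params(),
                        param_subset = as.vector(outer(c("V_", "a_"),
                          c("B", "P", "R", "O", "C", "K"), paste0)),
                        n_starts = 30, n_best = 10, spread = 3, seed = 1,
                        sim_dt = 0.5, maxit = 200) {
  stopifnot(all(c("gene", "time_h", "value") %in% names(data)),
            n_starts >= n_best)
  th0 <- unclass(clock_params(init))
  stopifnot(all(param_subset %in% names(th0)))
  set.seed(as.integer(seed))

  genes <- intersect(clock_genes(), unique(data$gene))
  obs <- lapply(genes, function(g) {
    d <- data[data$gene == g, ]
    list(t = d$time_h, v = d$value,
         w = 1 / max(stats::var(d$value), 1e-12))
  })
  names(obs) <- genes
  t_max <- max(data$time_h)

  cost <- function(lp) {
    th <- th0
    th[param_subset] <- exp(lp)
    tr <- tryCatch(simulate_clock(clock_params(th), hours = t_max,
                                  dt = sim_dt),
                   error = function(e) NULL)
    if (is.null(tr)) return(1e8)
    sc <- th[["obs_scale"]]
    tot <- 0
    for (g in genes) {
      sim <- stats::approx(tr$time, tr$states[, gene_state(g)],
                           xout = obs[[g]]$t)$y * sc
      tot <- tot + obs[[g]]$w * sum((sim - obs[[g]]$v)^2)
    }
    tot
  }

  lp0 <- log(th0[param_subset])
  lower <- lp0 - log(10); upper <- lp0 + log(10)
  hill <- intersect(param_subset, .hill_coef_names)
  lower[hill] <- pmax(lower[hill], 0)
  starts <- matrix(lp0, 1, length(lp0))
  if (n_starts > 1) {
    jitter <- matrix(stats::runif(length(lp0) * (n_starts - 1),
                                  -log(spread), log(spread)),
                     n_starts - 1, length(lp0))
    starts <- rbind(starts,
                    sweep(jitter, 2, lp0, `+`))
  }
  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    o <- tryCatch(stats::optim(starts[i, ], cost, method = "L-BFGS-B",
                               lower = lower, upper = upper,
                               control = list(maxit = maxit)),
                  error = function(e) NULL)
    if (is.null(o)) next
    th <- th0; th[param_subset] <- exp(o$par)
    fits[[i]] <- list(params = clock_params(th), cost = o$value,
                      convergence = o$convergence)
  }
  fits <- Filter(Negate(is.null), fits)
  fits <- fits[order(vapply(fits, `[[`, numeric(1), "cost"))]
  keep <- list()
  for (f in fits) {
    tr <- tryCatch(simulate_clock(f$params, hours = 48, dt = 0.5),
                   error = function(e) NULL)
    if (!is.null(tr) && isTRUE(accept_clock(tr))) keep <- c(keep, list(f))
    if (length(keep) == n_best) break
  }
  if (length(keep) < n_best) {
    stop("only ", length(keep), " oscillatory optima found (need ", n_best,
         "); increase n_starts")
  }
  out <- lapply(keep, `[[`, "params")
  attr(out, "fits") <- lapply(keep, function(f) f[c("cost", "convergence")])
  out
}
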