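#' Gene names of the clock model
#' @return Character vector of the six modelled genes.
#' @export
clock_genes <- function() c("Bmal1", "Per2", "Rev-Erba", "Rorg", "Cry1", "Clock")

# mRNA state for each gene
gene_state <- function(gene) {
  map <- c(Bmal1 = "mB", Per2 = "mP", `Rev-Erba` = "mR",
           Rorg = "mO", Cry1 = "mC", Clock = "mK")
  out <- map[gene]
  if (any(is.na(out))) stop("unknown gene: ", paste(gene[is.na(out)], collapse = ", "))
  unname(out)
}

# index used by the compiled RHS to select the forced gene
gene_code <- function(gene) {
  code <- c(Bmal1 = 1, Per2 = 2, `Rev-Erba` = 3)[gene]
  if (is.na(code)) stop("forcing is only supported for Bmal1, Per2 and Rev-Erba")
  unname(code)
}

#' Transcription-rate multiplier of a clock gene
#'
#' Dimensionless modulation of the basal transcription rate by the nuclear
#' modulator species. For Bmal1 the multiplier is
#' `(1 + g1 (ROR/g2)^g3) / (1 + (REV/g4)^g5 + (ROR/g2)^g3)`:
#' activation by ROR, repression by REV-ERB. Per2, Rev-Erba and Rorg are
#' activated by CLOCK/BMAL whose activity is attenuated by PER/CRY; Cry1 is
#' additionally repressed by REV-ERB.
#'
#' @param gene One of `"Bmal1"`, `"Per2"`, `"Rev-Erba"`, `"Rorg"`, `"Cry1"`,
#'   `"Clock"` (`"Clock"` is constitutive, multiplier 1).
#' @param M Named numeric vector of modulator concentrations (`pREV`, `pROR`,
#'   `pCB`, `pPC`), or a matrix with those columns for a whole time course.
#' @param params A [clock_params()] vector (only its Hill parameters are used).
#' @return Numeric multiplier(s), one per row of `M`.
#' @export
#' @examples
#' th <- default_clock_params()
#' transcription_rate("Bmal1", c(pREV = 0, pROR = 0, pCB = 1, pPC = 1), th)
transcription_rate <- function(gene, M, params) {
  gene <- match.arg(gene, clock_genes())
  if (is.null(dim(M))) M <- matrix(M, nrow = 1, dimnames = list(NULL, names(M)))
  need <- switch(gene,
    Bmal1 = c("pREV", "pROR"),
    Clock = character(0),
    c("pCB", "pPC"))
  if (gene == "Cry1") need <- c(need, "pREV")
  if (!all(need %in% colnames(M))) {
    stop("M must provide columns: ", paste(need, collapse = ", "))
  }
  if (any(M[, need, drop = FALSE] < 0)) stop("negative modulator concentrations")
  p <- as.list(unclass(params))
  if (gene == "Clock") return(rep(1, nrow(M)))
  if (gene == "Bmal1") {
    ror <- (M[, "pROR"] / p$g2)^p$g3
    rev <- (M[, "pREV"] / p$g4)^p$g5
    return(unname((1 + p$g1 * ror) / (1 + rev + ror)))
  }
  act <- M[, "pCB"] / (1 + (M[, "pPC"] / p$k_I)^p$h_I)
  fk <- switch(gene,
    Per2 = c(p$f_P, p$k_P), `Rev-Erba` = c(p$f_R, p$k_R),
    Rorg = c(p$f_O, p$k_O), Cry1 = c(p$f_C, p$k_C))
  u <- (act / fk[2])^p$h_a
  if (gene == "Cry1") {
    unname((1 + fk[1] * u) / (1 + u + (M[, "pREV"] / p$k_RC)^p$h_RC))
  } else {
    unname((1 + fk[1] * u) / (1 + u))
  }
}

# Reference R implementation of the RHS (cross-checked against the compiled
# version in the tests; the compiled one is used for ensembles).
clock_rhs_r <- function(t, x, parms) {
  p <- parms$p
  f <- if (is.null(parms$forcing)) 1 else parms$forcing(t)
  target <- parms$target %||% 0L
  hyp <- parms$hyp %||% 0L
  xx <- pmax(x, 0)
  M <- matrix(xx[c("pREV", "pROR", "pCB", "pPC")], nrow = 1,
              dimnames = list(NULL, c("pREV", "pROR", "pCB", "pPC")))
  tr <- vapply(c("Bmal1", "Per2", "Rev-Erba", "Rorg", "Cry1"),
               function(g) transcription_rate(g, M, p), numeric(1))
  fT <- rep(1, 3); fD <- rep(1, 3)
  if (target >= 1 && hyp == 1) fT[target] <- f
  if (target >= 1 && hyp == 2) fD[target] <- f
  with(as.list(c(x, unclass(p))), {
    list(c(
      fT[1] * V_B * tr[["Bmal1"]] - fD[1] * a_B * mB,
      fT[2] * V_P * tr[["Per2"]] - fD[2] * a_P * mP,
      fT[3] * V_R * tr[["Rev-Erba"]] - fD[3] * a_R * mR,
      V_O * tr[["Rorg"]] - a_O * mO,
      V_C * tr[["Cry1"]] - a_C * mC,
      V_K - a_K * mK,
      p_K * mK - d_KC * pKC - k_ass * pKC * pBC,
      p_B * mB - d_BC * pBC - k_ass * pKC * pBC,
      k_ass * pKC * pBC - d_CB * pCB,
      q_P * mP - d_PER * pPER - k_pc * pPER * pCRY,
      q_C * mC - d_CRY * pCRY - k_pc * pPER * pCRY,
      k_pc * pPER * pCRY - (d_PCc + k_tPC) * pPCc,
      k_tPC * pPCc - d_PC * pPC,
      p_REV * mR - d_REV * pREV,
      p_ROR * mO - d_ROR * pROR
    ))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the clock model
#'
#' Integrates the 13-state model with a stiff-capable solver from a fixed
#' initial state, discards a burn-in (transient) and returns the requested
#' window. Optionally a periodic scalar forcing multiplies the transcription
#' (hypothesis H1) or degradation (H2) term of one target gene.
#'
#' @param params A [clock_params()] vector.
#' @param hours Length of the returned window (h).
#' @param dt Output grid step (h).
#' @param burn_in_h Discarded transient (default 300 h; the gentle limit cycle converges slowly).
#' @param forcing Optional two-column matrix/data.frame `(time_h, value)`
#'   describing f(t) on one period; it is extended periodically over the
#'   whole integration span.
#' @param target_gene Gene whose equation receives the forcing
#'   (`"Bmal1"`, `"Per2"` or `"Rev-Erba"`).
#' @param hypothesis `"H1"` (transcription) or `"H2"` (degradation).
#' @param engine `"c"` (compiled, default) or `"r"` (reference R version).
#' @param rtol,atol Solver tolerances.
#' @param x0 Optional named initial state ([clock_state_names()] order).
#'   The default fixed state, together with the long burn-in, lands on the
#'   limit cycle; passing the state of a reference simulation with
#'   `burn_in_h = 0` anchors a perturbed clock to the reference phase
#'   (used by the residual-ensemble stage).
#' @return A `clock_trajectory`: list with `time` (h, starting at 0),
#'   `states` (matrix, columns [clock_state_names()]), and the call
#'   parameters. Time 0 of the output corresponds to the end of burn-in.
#' @export
#' @examples
#' tr <- simulate_clock(default_clock_params(), hours = 48)
#' rhythm_metrics(tr, "mB")$period
simulate_clock <- function(params, hours = 48, dt = 0.25, burn_in_h = 300,
                           forcing = NULL, target_gene = NULL,
                           hypothesis = NULL, engine = c("c", "r"),
                           rtol = 1e-8, atol = 1e-10, x0 = NULL) {
  engine <- match.arg(engine)
  params <- clock_params(params)
  target <- 0L; hyp <- 0L
  if (!is.null(forcing)) {
    if (is.null(target_gene) || is.null(hypothesis)) {
      stop("forcing requires target_gene and hypothesis")
    }
    target <- gene_code(target_gene)
    hyp <- match(match.arg(hypothesis, c("H1", "H2")), c("H1", "H2"))
  }
  times <- seq(0, burn_in_h + hours, by = dt)
  nst <- length(clock_state_names())
  if (is.null(x0)) {
    x0 <- setNames(rep(0.5, nst), clock_state_names())
  } else {
    stopifnot(length(x0) == nst)
    x0 <- setNames(as.numeric(x0[clock_state_names()]), clock_state_names())
  }

  if (!is.null(forcing)) {
    forcing <- as.matrix(forcing)
    if (ncol(forcing) != 2) stop("forcing must have columns (time_h, value)")
    ffun <- periodic_interp(forcing[, 1], forcing[, 2], period = 24)
    fvals <- ffun(times)
    if (any(fvals <= 0)) {
      stop("forcing multiplier is non-positive (min = ",
           signif(min(fvals), 4), "); rescale the forcing")
    }
  } else {
    fvals <- rep(1, length(times))
  }

  if (engine == "c") {
    pvec <- c(unclass(params), target = target, hyp = hyp)
    out <- deSolve::ode(
      y = x0, times = times, parms = pvec,
      func = "clock_derivs", dllname = "circlock",
      initfunc = "clock_initmod", initforc = "clock_initforc",
      forcings = cbind(times, fvals),
      method = "lsoda", rtol = rtol, atol = atol)
  } else {
    ffun <- approxfun(times, fvals, rule = 2)
    out <- deSolve::ode(
      y = x0, times = times,
      func = clock_rhs_r,
      parms = list(p = params, forcing = ffun, target = target, hyp = hyp),
      method = "lsoda", rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0 || any(!is.finite(out))) {
    stop("clock integration failed; parameters: ",
         paste(sprintf("%s=%.3g", names(params), params), collapse = ", "))
  }
  keep <- out[, "time"] >= burn_in_h
  states <- out[keep, clock_state_names(), drop = FALSE]
  if (min(states) < -1e-6) {
    stop("negative concentrations beyond solver tolerance")
  }
  states[states < 0] <- 0
  structure(list(time = out[keep, "time"] - burn_in_h, states = states,
                 params = params, dt = dt, hours = hours,
                 forced = !is.null(forcing),
                 target_gene = target_gene, hypothesis = hypothesis),
            class = "clock_trajectory")
}

#' @export
print.clock_trajectory <- function(x, ...) {
  cat("<clock_trajectory> ", length(x$time), " points over ", x$hours,
      " h (dt = ", x$dt, " h)", if (x$forced) " [forced]", "\n", sep = "")
  invisible(x)
}

# periodic linear interpolation of values sampled on [0, period)
periodic_interp <- function(t, v, period = 24) {
  tm <- t %% period
  o <- order(tm)
  tm <- tm[o]; v <- v[o]
  dup <- duplicated(tm)
  tm <- tm[!dup]; v <- v[!dup]
  # wrap for continuity
  tt <- c(tm[length(tm)] - period, tm, tm[1] + period)
  vv <- c(v[length(v)], v, v[1])
  function(x) approx(tt, vv, xout = x %% period)$y
}

#' Rhythm metrics of a simulated state variable
#'
#' Period is the mean spacing of successive maxima (quadratically
#' interpolated between grid points); phase is the time of the maximum on
#' the last full cycle, in `[0, period)`; relative amplitude is
#' `(max - min) / mean` over the last cycle; the circadian mean is taken
#' over the same cycle.
#'
#' @param traj A `clock_trajectory`.
#' @param variable State name (see [clock_state_names()]).
#' @return List with `period`, `relamp`, `phase`, `mean`, and logical
#'   `rhythmic` (FALSE for flat signals, relative amplitude < 1e-6, in which
#'   case the other entries are `NA`).
#' @export
rhythm_metrics <- function(traj, variable) {
  t <- traj$time
  x <- traj$states[, variable]
  m_all <- mean(x)
  if (m_all <= 0 || (max(x) - min(x)) / m_all < 1e-6) {
    return(list(period = NA_real_, relamp = 0, phase = NA_real_,
                mean = m_all, rhythmic = FALSE))
  }
  pk <- find_peaks(t, x)
  if (length(pk) < 2) {
    return(list(period = NA_real_, relamp = NA_real_, phase = NA_real_,
                mean = m_all, rhythmic = FALSE))
  }
  period <- mean(diff(pk))
  last <- t >= (max(t) - period)
  xl <- x[last]
  m <- mean(xl)
  relamp <- (max(xl) - min(xl)) / m
  phase <- pk[length(pk)] %% period
  list(period = period, relamp = relamp, phase = phase, mean = m,
       rhythmic = TRUE)
}

# interior maxima with parabolic sub-grid refinement
find_peaks <- function(t, x) {
  n <- length(x)
  i <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1
  i <- i[i > 1 & i < n]
  if (!length(i)) return(numeric(0))
  vapply(i, function(j) {
    y1 <- x[j - 1]; y2 <- x[j]; y3 <- x[j + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (abs(den) < 1e-300) 0 else 0.5 * (y1 - y3) / den
    t[j] + off * (t[j + 1] - t[j])
  }, numeric(1))
}

#' Circular distance between two phases
#'
#' @param ph1,ph2 Phases (h).
#' @param period Cycle length (h).
#' @return Distance on the circle, in `[0, period/2]`.
#' @export
phase_distance <- function(ph1, ph2, period) {
  d <- abs(ph1 - ph2) %% period
  min(d, period - d)
}
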