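#' @useDynLib circlock
#' @importFrom stats setNames approxfun approx optim rnorm runif sd
NULL

#' State variables of the clock model
#'
#' Fifteen states: the six clock gene mRNAs (Bmal1, Per2, Rev-Erba, Rorg,
#' Cry1, Clock), cytoplasmic CLOCK and BMAL1 proteins, the nuclear
#' CLOCK/BMAL activator complex, cytoplasmic PER and CRY proteins, the
#' cytoplasmic and nuclear PER/CRY repressor complexes, and the nuclear
#' REV-ERB and ROR proteins. The PER/CRY arm is deliberately a long
#' cascade (mRNA, protein, complex, nuclear transport): the phase lag that
#' sustains the oscillation comes from cascade length rather than from
#' steep Hill kinetics, keeping the limit cycle smooth.
#'
#' @return Character vector of state names in integration order.
#' @export
clock_state_names <- function() {
  c("mB", "mP", "mR", "mO", "mC", "mK",
    "pKC", "pBC", "pCB", "pPER", "pCRY", "pPCc", "pPC", "pREV", "pROR")
}

#' Modulator species driving clock gene transcription
#'
#' REV-ERB and ROR modulate Bmal1; CLOCK/BMAL and PER/CRY modulate Per2,
#' Cry1, Rev-Erba and Rorg.
#'
#' @return Character vector of modulator state names.
#' @export
clock_modulators <- function() c("pREV", "pROR", "pCB", "pPC")

#' Parameter names of the clock model, in canonical order
#'
#' Per-gene maximal transcription rates `V_*` (conc/h) and linear mRNA
#' degradation rates `a_*` (1/h); Hill parameters of the Bmal1 promoter
#' (`g1` fold-transcription ratio, `g2`/`g4` modulation ratios for ROR/REV,
#' `g3`/`g5` Hill coefficients); fold ratios `f_*` and activation thresholds
#' `k_*` for the CLOCK/BMAL-activated genes with shared Hill coefficient
#' `h_a`; PER/CRY inhibition threshold `k_I` and coefficient `h_I`; REV-ERB
#' repression of Cry1 (`k_RC`, `h_RC`); protein production, association /
#' nuclear-transport and degradation rates; and an observation scale factor
#' `obs_scale` mapping simulated concentrations to measured intensities
#' (not part of the dynamics).
#'
#' @return Character vector of 49 parameter names.
#' @export
clock_param_names <- function() {
  c("V_B", "V_P", "V_R", "V_O", "V_C", "V_K",
    "a_B", "a_P", "a_R", "a_O", "a_C", "a_K",
    "g1", "g2", "g3", "g4", "g5",
    "f_P", "k_P", "f_R", "k_R", "f_O", "k_O", "f_C", "k_C",
    "h_a", "k_I", "h_I", "k_RC", "h_RC",
    "p_K", "p_B", "k_ass", "d_KC", "d_BC", "d_CB",
    "q_P", "q_C", "d_PER", "d_CRY", "k_pc", "d_PCc", "k_tPC", "d_PC",
    "p_REV", "d_REV", "p_ROR", "d_ROR",
    "obs_scale")
}

# Hill exponents must stay >= 1 for a sigmoidal response
.hill_coef_names <- c("g3", "g5", "h_a", "h_I", "h_RC")

#' Reference parameter set of the clock model
#'
#' A versioned fixture tuned so that the unforced model settles on a limit
#' cycle with a period near 24 h, relative amplitudes above 5% for all
#' non-constitutive states, and antagonist phase separations (REV-ERB vs ROR,
#' PER/CRY vs CLOCK/BMAL) above 6 h.
#'
#' @return A `clock_params` object (named numeric vector).
#' @export
#' @examples
#' th <- default_clock_params()
#' th[["V_B"]]
default_clock_params <- function() {
  p <- c(
    V_B = 0.169021, V_P = 0.1075418, V_R = 0.1225871, V_O = 0.0277367,
    V_C = 0.1868556, V_K = 0.2,
    a_B = 0.2817017, a_P = 0.3021655, a_R = 0.8814709, a_O = 0.0779332,
    a_C = 0.3021655, a_K = 0.2,
    g1 = 4, g2 = 1, g3 = 1.5, g4 = 1.4479602, g5 = 2.5652409,
    f_P = 7.8946898, k_P = 0.7055468, f_R = 24.5845118, k_R = 0.7055468,
    f_O = 7.8946898, k_O = 0.7055468, f_C = 7.8946898, k_C = 0.7055468,
    h_a = 3, k_I = 1, h_I = 9.8341661, k_RC = 1.4479602, h_RC = 1.5,
    p_K = 0.5195667, p_B = 0.7229719, k_ass = 0.6323229,
    d_KC = 0.4068104, d_BC = 0.4068104, d_CB = 0.3161615,
    q_P = 0.2224623, q_C = 0.2224623, d_PER = 0.0558704, d_CRY = 0.0558704,
    k_pc = 0.1665919, d_PCc = 0.0333184, k_tPC = 0.1332735, d_PC = 0.1409707,
    p_REV = 0.9334274, d_REV = 0.9334274, p_ROR = 0.0641331, d_ROR = 0.0641331,
    obs_scale = 1
  )
  clock_params(p)
}

#' Construct and validate a clock parameter vector
#'
#' @param x Named numeric vector covering all names in [clock_param_names()].
#' @return A validated `clock_params` object.
#' @export
clock_params <- function(x) {
  nm <- clock_param_names()
  if (is.null(names(x)) || !all(nm %in% names(x))) {
    missing <- setdiff(nm, names(x))
    stop("clock_params: missing parameters: ", paste(missing, collapse = ", "))
  }
  x <- x[nm]
  vmax <- paste0("V_", c("B", "P", "R", "O", "C", "K"))
  if (any(!is.finite(x)) || any(x < 0) || any(x[setdiff(nm, vmax)] <= 0)) {
    stop("clock_params: parameters must be finite and strictly positive ",
         "(maximal transcription rates V_* may be zero)")
  }
  if (any(x[.hill_coef_names] < 1)) {
    stop("clock_params: Hill coefficients (",
         paste(.hill_coef_names, collapse = ", "), ") must be >= 1")
  }
  structure(x, class = c("clock_params", "numeric"))
}

#' Read / write clock parameters as JSON
#'
#' @param path File path.
#' @param params A `clock_params` object.
#' @return `read_clock_params` returns a `clock_params` object;
#'   `write_clock_params` returns `path` invisibly.
#' @export
read_clock_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  clock_params(unlist(x))
}

#' @rdname read_clock_params
#' @export
write_clock_params <- function(params, path) {
  jsonlite::write_json(as.list(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
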