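#' Class factor design
#'
#' Classes 1-4 form a 2x2 sex-by-strain design: 1 = female/strain A,
#' 2 = male/strain A, 3 = female/strain B, 4 = male/strain B.
#'
#' @param class_id Integer vector in 1..4.
#' @return data.frame with factors `sex` and `strain`.
#' @export
class_design <- function(class_id) {
  stopifnot(all(class_id %in% 1:4))
  data.frame(
    sex = factor(c("female", "male", "female", "male")[class_id],
                 levels = c("female", "male")),
    strain = factor(c("A", "A", "B", "B")[class_id], levels = c("A", "B")))
}

#' Collect per-trajectory fitted weights of one model
#'
#' @param S Integer feature subset.
#' @param panels List of 4 `regulator_panel`s.
#' @param ens A `residual_ensemble`.
#' @return data.frame `class`, `trajectory`, `feature`, `weight`.
#' @export
collect_weights <- function(S, panels, ens) {
  n <- dim(ens$y)[1]
  out <- lapply(1:4, function(ci) {
    b <- fit_model(S, panels[[ci]], ensemble_matrix(ens, ci))$beta
    data.frame(class = ci,
               trajectory = rep(seq_len(n), each = length(S)),
               feature = rep(regulator_features()[S], times = n),
               weight = as.numeric(b))
  })
  do.call(rbind, out)
}

#' Two-way ANOVA on regulator weights
#'
#' Fixed-effects sex x strain ANOVA (with interaction) on the fitted
#' weights of each feature of one model, treating per-trajectory weights as
#' realizations of a random variable. Trajectories of an ensemble are
#' pseudo-replicates, not independent animals; the returned table carries a
#' `pseudo_replicates` attribute as a caveat flag.
#'
#' @param weights data.frame from [collect_weights()] (all four classes,
#'   at least 2 trajectories each).
#' @return data.frame `feature`, `term` (sex / strain / interaction), `F`,
#'   `p`.
#' @export
anova_weights <- function(weights) {
  counts <- table(weights$class)
  if (length(counts) < 4 || any(counts == 0)) {
    stop("all four classes are required (empty cell)")
  }
  des <- class_design(weights$class)
  weights <- cbind(weights, des)
  out <- lapply(split(weights, weights$feature), function(d) {
    if (min(table(d$class)) < 2) stop("need >= 2 trajectories per class")
    fit <- stats::aov(weight ~ sex * strain, data = d)
    tab <- summary(fit)[[1]]
    data.frame(feature = d$feature[1],
               term = c("sex", "strain", "interaction"),
               F = tab[1:3, "F value"], p = tab[1:3, "Pr(>F)"])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "pseudo_replicates") <- TRUE
  res
}

#' Kernel-density summaries of weight distributions per class
#'
#' Gaussian kernel with the rule-of-thumb bandwidth; modes are the local
#' maxima of the estimated density.
#'
#' @param weights data.frame from [collect_weights()].
#' @param feature Feature name.
#' @return Named list per class: `density` (a [stats::density] object) and
#'   `modes` (locations of local maxima, highest first).
#' @export
weight_density <- function(weights, feature) {
  d <- weights[weights$feature == feature, ]
  out <- lapply(split(d$weight, d$class), function(w) {
    if (length(w) < 10) stop("need >= 10 samples per class")
    if (stats::sd(w) == 0) {
      return(list(density = NULL, modes = w[1]))
    }
    den <- stats::density(w, bw = "nrd0")
    y <- den$y
    loc <- which(diff(sign(diff(y))) == -2) + 1
    if (!length(loc)) loc <- which.max(y)
    loc <- loc[order(-y[loc])]
    list(density = den, modes = den$x[loc])
  })
  names(out) <- paste0("class", names(out))
  out
}

#' Profile likelihood of one weight in a fitted model
#'
#' Fixes `beta_j` on a grid around the optimum, re-optimizes the remaining
#' weights, and maps the loss profile to an identifiability verdict: the
#' weight is identifiable iff the profile crosses the threshold
#' `loss_min * (1 + qchisq(conf, 1) / (N - |S|))` on both sides of the
#' optimum inside the grid (Gaussian-error mapping between loss ratios and
#' the chi-square quantile). A profile that stays below the threshold on
#' either side is `"non-identifiable"` if flat, `"inconclusive"` if the
#' grid is simply too narrow.
#'
#' @param S Integer feature subset.
#' @param panel A `regulator_panel`.
#' @param y One residual trajectory (length N-1).
#' @param feature Feature (name or index into `S`'s features) to profile.
#' @param grid_values Grid of fixed values; default 41 points spanning
#'   +/- 5 fitted-sd of the weight (from the covariance of the LS fit).
#' @param conf Confidence level (default 0.95).
#' @return List with `grid`, `profile` (loss at each fixed value),
#'   `loss_min`, `threshold`, `verdict`.
#' @export
profile_likelihood <- function(S, panel, y, feature, grid_values = NULL,
                               conf = 0.95) {
  feats <- regulator_features()[S]
  j <- if (is.character(feature)) match(feature, feats) else feature
  if (is.na(j) || j < 1 || j > length(S)) stop("feature not in model")
  nt <- length(y)
  Z <- panel$z[seq_len(nt), S, drop = FALSE]
  fit <- fit_model(S, panel, y)
  bhat <- fit$beta[, 1]
  loss_min <- fit$loss[1]
  if (is.null(grid_values)) {
    XtX <- crossprod(Z)
    sigma2 <- loss_min * nt / max(1, nt - length(S))
    se <- sqrt(diag(tryCatch(solve(XtX), error = function(e) pracma::pinv(XtX))) *
                 sigma2)[j]
    if (!is.finite(se) || se == 0) se <- max(abs(bhat[j]), 1) * 0.5
    grid_values <- bhat[j] + seq(-5, 5, length.out = 41) * se
  }
  others <- setdiff(seq_along(S), j)
  prof <- vapply(grid_values, function(bj) {
    r <- y - Z[, j] * bj
    if (length(others)) {
      b <- qr.coef(qr(Z[, others, drop = FALSE]), r)
      b[is.na(b)] <- 0
      r <- r - Z[, others, drop = FALSE] %*% b
    }
    mean(r^2)
  }, numeric(1))
  threshold <- loss_min * (1 + stats::qchisq(conf, 1) / max(1, nt - length(S)))
  left <- any(prof[grid_values < bhat[j]] > threshold)
  right <- any(prof[grid_values > bhat[j]] > threshold)
  flat <- diff(range(prof)) <= max(1e-12, 1e-9 * max(loss_min, 1e-12))
  verdict <- if (left && right) {
    "identifiable"
  } else if (flat) {
    "non-identifiable"
  } else {
    "inconclusive"
  }
  list(grid = grid_values, profile = prof, loss_min = loss_min,
       threshold = threshold, verdict = verdict, beta_hat = bhat[j])
}

#' Sign-constrained refit of a model over an ensemble
#'
#' Enforces a common weight sign per feature across all classes and
#' trajectories, re-optimizing each trajectory by non-negative least
#' squares on sign-flipped columns. The template is either given (`"+"` /
#' `"-"` per feature) or derived by majority vote over the unconstrained
#' fits (`"auto"`).
#'
#' @param S Integer feature subset.
#' @param panels List of 4 `regulator_panel`s.
#' @param ens A `residual_ensemble`.
#' @param template Character vector of `"+"`/`"-"` per feature, or
#'   `"auto"`.
#' @return List with `E_unconstrained`, `E_constrained`, `ratio`,
#'   `template`, and `beta` (list per class of constrained weights).
#' @export
constrained_refit <- function(S, panels, ens, template = "auto") {
  n <- dim(ens$y)[1]; nt <- dim(ens$y)[2]
  fits <- lapply(1:4, function(ci) fit_model(S, panels[[ci]], ensemble_matrix(ens, ci)))
  if (identical(template, "auto")) {
    allb <- do.call(cbind, lapply(fits, `[[`, "beta"))
    template <- ifelse(rowMeans(allb > 0) >= 0.5, "+", "-")
  }
  if (length(template) != length(S) || !all(template %in% c("+", "-"))) {
    stop("template must give '+' or '-' for each of the ", length(S),
         " features")
  }
  signs <- ifelse(template == "+", 1, -1)
  E_unc <- mean(vapply(fits, function(f) mean(f$loss), numeric(1)))
  beta_c <- vector("list", 4)
  loss_c <- 0
  for (ci in 1:4) {
    Z <- panels[[ci]]$z[seq_len(nt), S, drop = FALSE]
    Zs <- sweep(Z, 2, signs, `*`)
    B <- matrix(0, length(S), n,
                dimnames = list(regulator_features()[S], NULL))
    for (k in seq_len(n)) {
      y <- ens$y[k, , ci]
      nn <- pracma::lsqnonneg(Zs, y)
      B[, k] <- signs * nn$x
      loss_c <- loss_c + mean((y - Z %*% B[, k])^2)
    }
    beta_c[[ci]] <- B
  }
  E_con <- loss_c / (4 * n)
  list(E_unconstrained = E_unc, E_constrained = E_con,
       ratio = E_con / E_unc, template = template, beta = beta_c)
}
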