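#' Enumerate admissible regulator models
#'
#' All subsets of the 10 features with 1 to `max_terms` members, excluding
#' any subset containing both a regulator and its integral (features `j` and
#' `j + 5`): a regulator may act directly or indirectly, not both. The
#' exclusion caps model size at 5; sizes 1..5 give 10, 40, 80, 80 and 32
#' models (242 in total). Deterministic lexicographic order.
#'
#' @param max_terms Maximum model size, 1..5.
#' @return List of integer vectors (feature indices, see
#'   [regulator_features()]).
#' @export
#' @examples
#' length(enumerate_models(5))
enumerate_models <- function(max_terms = 5) {
  if (max_terms < 1 || max_terms > 5) {
    stop("max_terms must be in 1..5 (a direct regulator excludes its ",
         "integral, so admissible models have at most 5 terms)")
  }
  out <- list()
  for (r in seq_len(max_terms)) {
    cmb <- utils::combn(10, r, simplify = FALSE)
    keep <- vapply(cmb, function(s) !anyDuplicated((s - 1) %% 5), logical(1))
    out <- c(out, cmb[keep])
  }
  out
}

model_id <- function(S) paste(regulator_features()[S], collapse = "+")

#' Least-squares fit of one regulator model to trajectories
#'
#' Ordinary least squares without intercept (inputs and outputs are both
#' standardized) restricted to the feature columns in `S`. The loss is the
#' mean squared residual over the grid; for the empty model it is the mean
#' square of `y` (equal to 1 for a standardized trajectory).
#'
#' @param S Integer feature subset (possibly empty).
#' @param panel A `regulator_panel` (its first N-1 rows are used to match
#'   the residual grid).
#' @param y Numeric vector of length N-1, or an (N-1) x n matrix of
#'   trajectories fitted jointly.
#' @return List with `beta` (|S| x n matrix, NULL for the empty model),
#'   `loss` (length-n vector) and logical `rank_deficient` (fit fell back
#'   to the pseudo-inverse).
#' @export
fit_model <- function(S, panel, y) {
  y <- as.matrix(y)
  X <- panel$z[seq_len(nrow(y)), S, drop = FALSE]
  if (length(S) == 0) {
    return(list(beta = NULL, loss = colMeans(y^2), rank_deficient = FALSE))
  }
  qrx <- qr(X)
  rank_def <- qrx$rank < ncol(X)
  beta <- if (rank_def) {
    pracma::pinv(X) %*% y
  } else {
    qr.coef(qrx, y)
  }
  beta <- matrix(beta, ncol = ncol(y),
                 dimnames = list(regulator_features()[S], NULL))
  res <- y - X %*% beta
  list(beta = beta, loss = colMeans(res^2), rank_deficient = rank_def)
}

#' Total error of a model over a residual ensemble
#'
#' Mean over the four classes and the n trajectories of the per-trajectory
#' minimized loss.
#'
#' @param S Integer feature subset.
#' @param panels List of 4 `regulator_panel`s.
#' @param ens A `residual_ensemble`.
#' @return Scalar total error E (in `[0, 1]` for standardized data).
#' @export
total_error <- function(S, panels, ens) {
  if (length(panels) != 4 || any(vapply(panels, is.null, logical(1)))) {
    stop("panels must contain all four classes")
  }
  mean(vapply(1:4, function(ci) {
    mean(fit_model(S, panels[[ci]], ensemble_matrix(ens, ci))$loss)
  }, numeric(1)))
}

#' Exhaustive search over all admissible models
#'
#' @param panels List of 4 `regulator_panel`s.
#' @param ens A `residual_ensemble`.
#' @param max_terms Maximum model size.
#' @return data.frame `model_id`, `size`, `E`, ordered by `E`, with the
#'   subsets in attribute `subsets` (aligned with the unsorted enumeration
#'   via column `enum_index`).
#' @export
search_models <- function(panels, ens, max_terms = 5) {
  subsets <- enumerate_models(max_terms)
  E <- vapply(subsets, total_error, numeric(1), panels = panels, ens = ens)
  d <- data.frame(enum_index = seq_along(subsets),
                  model_id = vapply(subsets, model_id, character(1)),
                  size = lengths(subsets), E = E)
  d <- d[order(d$E), ]
  rownames(d) <- NULL
  attr(d, "subsets") <- subsets
  d
}

#' Mean absolute Shapley values over the admissible 5-feature models
#'
#' For every admissible 5-feature subset the model is fitted per class and
#' per trajectory; the Shapley value of feature `j` at time `t_i` for a
#' linear fit with baseline at the feature means (zero after
#' standardization) is `phi_j(t_i) = beta_j z_j(t_i)`. Absolute values are
#' averaged over time points, trajectories, classes and the subsets
#' containing the feature.
#'
#' @param panels List of 4 `regulator_panel`s.
#' @param ens A `residual_ensemble`.
#' @return data.frame `feature`, `phi` (mean absolute Shapley value), `sd`
#'   (across trajectories), `n_subsets`; melatonin rows are always present
#'   (the negative control is evaluated, never dropped a priori).
#' @export
shapley_table <- function(panels, ens) {
  subsets <- Filter(function(s) length(s) == 5, enumerate_models(5))
  n <- dim(ens$y)[1]
  acc <- matrix(0, 10, 0)   # per-trajectory mean |phi| accumulators
  per_feature <- vector("list", 10)
  for (S in subsets) {
    # |phi| averaged over time for each trajectory and class
    phi_tc <- array(NA_real_, c(length(S), n, 4))
    for (ci in 1:4) {
      fit <- fit_model(S, panels[[ci]], ensemble_matrix(ens, ci))
      Z <- panels[[ci]]$z[seq_len(dim(ens$y)[2]), S, drop = FALSE]
      for (jj in seq_along(S)) {
        phi_tc[jj, , ci] <- colMeans(abs(outer(Z[, jj], fit$beta[jj, ])))
      }
    }
    for (jj in seq_along(S)) {
      j <- S[jj]
      per_feature[[j]] <- c(per_feature[[j]], list(phi_tc[jj, , ]))
    }
  }
  phi <- vapply(per_feature, function(l) mean(unlist(l)), numeric(1))
  sds <- vapply(seq_len(10), function(j) {
    # spread across trajectories of the per-trajectory mean (over classes
    # and subsets) absolute Shapley value
    m <- Reduce(`+`, lapply(per_feature[[j]], function(a) rowMeans(a)))
    stats::sd(m / length(per_feature[[j]]))
  }, numeric(1))
  data.frame(feature = regulator_features(), phi = phi, sd = sds,
             n_subsets = vapply(per_feature, length, integer(1)))
}

#' Exhaustive Shapley value of one fitted linear model
#'
#' Brute-force evaluation of the coalition-weighted average over all
#' subsets of the other features, for the value function that keeps the
#' full fitted coefficients and drops the excluded features (features
#' outside the coalition contribute their mean, zero after
#' standardization). Serves as the oracle for the linear shortcut
#' `phi_j(t) = beta_j z_j(t)`.
#'
#' @param beta Named fitted weights of the full model (length m).
#' @param Z N x m matrix of the model's feature columns.
#' @param j Index (into `beta`) of the feature to attribute.
#' @return Numeric vector `phi_j(t)` of length N.
#' @export
shapley_exact <- function(beta, Z, j) {
  m <- length(beta)
  others <- setdiff(seq_len(m), j)
  phi <- numeric(nrow(Z))
  for (sz in 0:length(others)) {
    w <- factorial(sz) * factorial(m - sz - 1) / factorial(m)
    combos <- if (sz == 0) list(integer(0)) else
      utils::combn(others, sz, simplify = FALSE)
    for (T in combos) {
      pred_with <- Z[, c(T, j), drop = FALSE] %*% beta[c(T, j)]
      pred_without <- if (length(T)) Z[, T, drop = FALSE] %*% beta[T] else 0
      phi <- phi + w * drop(pred_with - pred_without)
    }
  }
  phi
}

#' Dominant term of a fitted model
#'
#' The feature maximizing the mean absolute weight across classes and
#' trajectories; ties go to the lower feature index with a warning.
#'
#' @param beta_list List of 4 matrices (|S| x n fitted weights per class).
#' @param S Integer feature subset (defines the feature indices).
#' @return Feature index (into [regulator_features()]).
#' @export
dominant_term <- function(beta_list, S) {
  m <- rowMeans(abs(do.call(cbind, beta_list)))
  mx <- max(m)
  hits <- which(m >= mx - 1e-12)
  if (length(hits) > 1) {
    warning("tie between features ",
            paste(regulator_features()[S[hits]], collapse = ", "),
            "; returning the lower index")
  }
  as.integer(S[min(hits)])
}

#' Nested-model F test across a trajectory ensemble
#'
#' Per trajectory, the standard F statistic from residual sums of squares
#' of two nested intercept-free fits with `(df1, df2) =
#' (|S_large| - |S_small|, N - 1 - |S_large|)`. Trajectories of an ensemble
#' are not independent replicates, so no pooled p-value is formed: the
#' median p and the fraction below 0.05 are reported.
#'
#' @param S_small,S_large Nested feature subsets.
#' @param panels List of 4 `regulator_panel`s.
#' @param ens A `residual_ensemble`.
#' @return List with `p_median`, `frac_sig`, and matrix `p` (n x 4).
#' @export
nested_f_test <- function(S_small, S_large, panels, ens) {
  if (!all(S_small %in% S_large)) stop("models are not nested")
  if (length(S_small) == length(S_large)) {
    stop("identical model sizes: F statistic undefined")
  }
  nt <- dim(ens$y)[2]
  df1 <- length(S_large) - length(S_small)
  df2 <- nt - length(S_large)
  if (df2 <= 0) stop("not enough time points for the large model")
  p <- sapply(1:4, function(ci) {
    y <- ensemble_matrix(ens, ci)
    rss_s <- fit_model(S_small, panels[[ci]], y)$loss * nt
    rss_l <- fit_model(S_large, panels[[ci]], y)$loss * nt
    f <- pmax(0, (rss_s - rss_l) / df1) / (rss_l / df2)
    stats::pf(f, df1, df2, lower.tail = FALSE)
  })
  list(p_median = stats::median(p), frac_sig = mean(p < 0.05), p = p)
}

#' Shuffled-timepoint cross-validation of one model
#'
#' Per trajectory, time points are shuffled and divided into `folds` folds;
#' the model is fitted on the training folds and evaluated on the held-out
#' fold. Reports the mean train and test losses, the overfitting
#' diagnostic.
#'
#' @param S Integer feature subset.
#' @param panels List of 4 `regulator_panel`s.
#' @param ens A `residual_ensemble`.
#' @param folds Number of folds (default 4).
#' @param seed Integer seed for the shuffles.
#' @return List with `train`, `test` (mean losses).
#' @export
cv_check <- function(S, panels, ens, folds = 4, seed = 1) {
  nt <- dim(ens$y)[2]
  if (nt < folds) stop("need at least as many time points as folds")
  set.seed(as.integer(seed))
  n <- dim(ens$y)[1]
  tr_loss <- te_loss <- 0; cnt <- 0
  for (ci in 1:4) {
    Z <- panels[[ci]]$z[seq_len(nt), S, drop = FALSE]
    for (k in seq_len(n)) {
      y <- ens$y[k, , ci]
      idx <- sample(nt)
      fold_of <- rep(seq_len(folds), length.out = nt)[order(idx)]
      for (f in seq_len(folds)) {
        tr <- fold_of != f
        b <- qr.coef(qr(Z[tr, , drop = FALSE]), y[tr])
        b[is.na(b)] <- 0
        tr_loss <- tr_loss + mean((y[tr] - Z[tr, , drop = FALSE] %*% b)^2)
        te_loss <- te_loss + mean((y[!tr] - Z[!tr, , drop = FALSE] %*% b)^2)
        cnt <- cnt + 1
      }
    }
  }
  list(train = tr_loss / cnt, test = te_loss / cnt)
}

#' Screen a regulation hypothesis
#'
#' Computes the best total error per model size (1..5), locates the elbow
#' (the size after which the error improvement drops most steeply), and
#' accepts the hypothesis iff the best model at the elbow size fits better
#' than `threshold`.
#'
#' @param panels List of 4 `regulator_panel`s.
#' @param ens A `residual_ensemble`.
#' @param threshold Admissibility threshold on E (default 0.15).
#' @return List with `best_by_size` (data.frame size/model_id/E),
#'   `elbow_size`, `verdict` (`"accepted"`/`"rejected"`), `best_E`.
#' @export
screen_hypothesis <- function(panels, ens, threshold = 0.15) {
  res <- search_models(panels, ens, max_terms = 5)
  best <- do.call(rbind, lapply(1:5, function(sz) {
    d <- res[res$size == sz, ]
    d[which.min(d$E), c("size", "model_id", "E")]
  }))
  rownames(best) <- NULL
  # steepest improvement between consecutive model sizes (1 -> 2, ..., 4 -> 5)
  elbow <- which.max(-diff(best$E)) + 1L
  bestE <- best$E[elbow]
  list(best_by_size = best, elbow_size = elbow,
       verdict = if (bestE <= threshold) "accepted" else "rejected",
       best_E = bestE, threshold = threshold, all_models = res)
}
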