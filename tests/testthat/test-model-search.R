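test_that("admissible model counts follow the constrained combinatorics", {
  sizes <- lengths(enumerate_models(5))
  expect_identical(sum(sizes == 1), 10L)
  expect_identical(sum(sizes == 2), 40L)
  expect_identical(sum(sizes == 3), 80L)
  expect_identical(sum(sizes == 4), 80L)
  expect_identical(sum(sizes == 5), 32L)
  expect_length(enumerate_models(5), 242)
  # no admissible subset pairs a regulator with its integral
  bad <- vapply(enumerate_models(5), function(s) {
    any(duplicated(ifelse(s > 5, s - 5, s)))
  }, logical(1))
  expect_false(any(bad))
  expect_error(enumerate_models(6), "max_terms")
  expect_error(enumerate_models(0), "max_terms")
})

test_that("empty model loss is exactly 1 on standardized trajectories", {
  pan <- toy_panel()
  set.seed(4)
  y <- std_pop(rnorm(length(common_grid()) - 1))
  f <- fit_model(integer(0), pan, y)
  expect_equal(f$loss, 1, tolerance = 1e-14)
})

test_that("least squares recovers exact linear combinations", {
  pan <- toy_panel()
  nt <- length(common_grid()) - 1
  S <- c(2, 8)
  beta <- c(1.3, -0.6)
  y <- drop(pan$z[seq_len(nt), S] %*% beta)
  f <- fit_model(S, pan, y)
  expect_lt(f$loss, 1e-20)
  expect_equal(unname(f$beta[, 1]), beta, tolerance = 1e-8)
  # agreement with an independent normal-equations solve on random designs
  set.seed(9)
  for (rep in 1:5) {
    S2 <- sample(10, 3)
    y2 <- rnorm(8)
    X <- pan$z[1:8, S2]
    b_ref <- solve(crossprod(X), crossprod(X, y2))
    f2 <- fit_model(S2, structure(list(z = pan$z[1:8, ], grid = pan$grid[1:8],
                                       scale = pan$scale, class_id = 1),
                                  class = "regulator_panel"), y2)
    expect_equal(unname(f2$beta[, 1]), unname(drop(b_ref)), tolerance = 1e-10)
  }
})

test_that("adding a feature never increases the loss", {
  pan <- toy_panel()
  set.seed(12)
  y <- std_pop(rnorm(length(common_grid()) - 1))
  l2 <- fit_model(c(1, 7), pan, y)$loss
  l3 <- fit_model(c(1, 7, 3), pan, y)$loss
  l1 <- fit_model(1, pan, y)$loss
  expect_lte(l3, l2 + 1e-12)
  expect_lte(l2, l1 + 1e-12)
})

test_that("rank-deficient designs fall back to the pseudo-inverse", {
  pan <- toy_panel()
  pan$z[, 2] <- pan$z[, 1]   # duplicate column
  f <- fit_model(c(1, 2), pan, std_pop(rnorm(length(common_grid()) - 1)))
  expect_true(f$rank_deficient)
  expect_true(all(is.finite(f$beta)))
})

test_that("total error matches a brute-force trajectory loop", {
  panels <- toy_panels()
  nt <- length(common_grid()) - 1
  set.seed(31)
  ys <- lapply(1:4, function(ci) {
    sapply(1:7, function(k) std_pop(
      drop(panels[[ci]]$z[seq_len(nt), c(3, 9)] %*% c(1, 0.5)) + rnorm(nt, 0, 0.4)))
  })
  ens <- stub_ensemble(ys)
  S <- c(3, 9)
  E <- total_error(S, panels, ens)
  brute <- mean(unlist(lapply(1:4, function(ci) {
    vapply(1:7, function(k) {
      X <- panels[[ci]]$z[seq_len(nt), S]
      b <- solve(crossprod(X), crossprod(X, ys[[ci]][, k]))
      mean((ys[[ci]][, k] - X %*% b)^2)
    }, numeric(1))
  })))
  expect_equal(E, brute, tolerance = 1e-12)
  expect_error(total_error(S, panels[1:3], ens), "four classes")
  # empty model: E = 1
  expect_equal(total_error(integer(0), panels, ens), 1, tolerance = 1e-12)
})

test_that("Shapley linear shortcut equals the exhaustive coalition formula", {
  pan <- toy_panel()
  nt <- length(common_grid()) - 1
  set.seed(17)
  y <- std_pop(rnorm(nt))
  five_sets <- Filter(function(s) length(s) == 5, enumerate_models(5))
  expect_length(five_sets, 32)
  for (S in five_sets) {
    f <- fit_model(S, pan, y)
    Z <- pan$z[seq_len(nt), S]
    beta <- f$beta[, 1]
    for (j in seq_along(S)) {
      exact <- shapley_exact(beta, Z, j)
      shortcut <- beta[j] * Z[, j]
      expect_equal(exact, unname(shortcut), tolerance = 1e-12)
    }
  }
})

test_that("Shapley table attributes zero to silent features", {
  panels <- toy_panels()
  nt <- length(common_grid()) - 1
  ys <- lapply(1:4, function(ci) matrix(0, nt, 3))  # y identically zero
  tab <- shapley_table(panels, stub_ensemble(ys))
  expect_identical(nrow(tab), 10L)
  expect_true(all(tab$phi < 1e-12))
  expect_true(all(c("melatonin", "int_melatonin") %in% tab$feature))
  expect_true(all(tab$n_subsets == 16))
})

test_that("dominant term maximizes mean absolute weight with tie rule", {
  b1 <- list(matrix(c(2, 1), 2, 5), matrix(c(2, 1), 2, 5),
             matrix(c(2, 1), 2, 5), matrix(c(2, 1), 2, 5))
  expect_identical(dominant_term(b1, c(4, 9)), 4L)
  b2 <- lapply(1:4, function(i) matrix(1, 2, 5))
  expect_warning(d <- dominant_term(b2, c(4, 9)), "tie")
  expect_identical(d, 4L)
})

test_that("nested F test is calibrated under the null and powered under truth", {
  panels <- toy_panels()
  nt <- length(common_grid()) - 1
  set.seed(23)
  n <- 300
  ys_null <- lapply(1:4, function(ci) {
    sapply(seq_len(n), function(k) std_pop(
      drop(panels[[ci]]$z[seq_len(nt), 1]) + rnorm(nt, 0, 1)))
  })
  ens_null <- stub_ensemble(ys_null)
  # adding a pure-noise column: per-trajectory p approximately uniform
  res <- nested_f_test(1, c(1, 4), panels, ens_null)
  expect_gt(stats::ks.test(as.vector(res$p), "punif")$p.value, 0.01)
  # adding the truly missing feature: overwhelming significance
  ys_sig <- lapply(1:4, function(ci) {
    sapply(1:20, function(k) std_pop(
      drop(panels[[ci]]$z[seq_len(nt), c(1, 4)] %*% c(1, 2)) +
        rnorm(nt, 0, 0.05)))
  })
  res2 <- nested_f_test(1, c(1, 4), panels, stub_ensemble(ys_sig))
  expect_lt(res2$p_median, 1e-6)
  expect_error(nested_f_test(c(1, 4), c(1, 2), panels, ens_null), "nested")
  expect_error(nested_f_test(c(1, 4), c(4, 1), panels, ens_null),
               "identical")
})

test_that("shuffled-timepoint cross-validation flags overfitting", {
  panels <- toy_panels()
  nt <- length(common_grid()) - 1
  # exact linear ground truth: train and test both near zero
  ys <- lapply(1:4, function(ci) {
    sapply(1:4, function(k) drop(panels[[ci]]$z[seq_len(nt), c(2, 6)] %*% c(1, -1)))
  })
  cv <- cv_check(c(2, 6), panels, stub_ensemble(ys), seed = 2)
  expect_lt(cv$train, 1e-20)
  expect_lt(cv$test, 1e-20)
  # pure noise with a 5-term model: test error above train error
  set.seed(5)
  ys_n <- lapply(1:4, function(ci) {
    sapply(1:6, function(k) std_pop(rnorm(nt)))
  })
  cv_n <- cv_check(c(1, 2, 3, 4, 5), panels, stub_ensemble(ys_n), seed = 3)
  expect_gt(cv_n$test, cv_n$train)
  # seed reproducibility
  expect_identical(cv_check(c(1, 2), panels, stub_ensemble(ys_n), seed = 7),
                   cv_check(c(1, 2), panels, stub_ensemble(ys_n), seed = 7))
})

test_that("hypothesis screening reports sizes, elbow and verdict", {
  fx <- study_fixture()
  ens <- study_ensemble(n = 20)
  sc <- screen_hypothesis(fx$panels, ens)
  expect_identical(nrow(sc$best_by_size), 5L)
  # error is non-increasing in model size
  expect_true(all(diff(sc$best_by_size$E) < 1e-12))
  expect_identical(sc$elbow_size, 2L)
  expect_identical(sc$verdict, "accepted")
})
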