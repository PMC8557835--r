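# Shared fixtures, built in code and cached per test session.

.cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# a smooth_series wrapper around explicit grid values (no GP fit needed)
make_smooth <- function(values, grid, label = NULL) {
  structure(list(grid = grid, mean = values, sd = rep(0, length(grid)),
                 hyper = c(sf = NA, ell = NA, sn = NA), period = 24,
                 label = label),
            class = "smooth_series")
}

# deterministic, well-conditioned panel: five waveforms with distinct
# phases and harmonic content
toy_panel <- function(class_id = 1, grid = common_grid(), jitter = 0) {
  ph <- c(2, 7, 12, 17, 21) + (class_id - 1) * 0.5
  h2 <- c(0.4, 0.15, 0.3, 0.2, 0.1)
  h3 <- c(0.15, 0.05, 0.1, 0.08, 0.05)
  w <- 2 * pi / 24
  feats <- regulator_features()[1:5]
  sm <- lapply(seq_along(feats), function(j) {
    v <- cos(w * (grid - ph[j])) +
      h2[j] * cos(2 * w * (grid - ph[j] - j)) +
      h3[j] * cos(3 * w * (grid - ph[j] + j))
    if (jitter > 0) v <- v + jitter * sin(w * grid * j + j)
    make_smooth(10 + 3 * v, grid, feats[j])
  })
  names(sm) <- feats
  build_panel(sm, class_id = class_id)
}

toy_panels <- function(grid = common_grid()) {
  lapply(1:4, toy_panel, grid = grid)
}

# ensemble stub with prescribed trajectories (bypasses the clock)
stub_ensemble <- function(y_list_by_class, grid = common_grid(),
                          gene = "Bmal1", hypothesis = "H1") {
  n <- ncol(y_list_by_class[[1]])
  nt <- nrow(y_list_by_class[[1]])
  y <- array(NA_real_, c(n, nt, 4))
  for (ci in 1:4) y[, , ci] <- t(y_list_by_class[[ci]])
  structure(list(y = y, gene = gene, hypothesis = hypothesis,
                 grid = grid[seq_len(nt)], acceptance_rate = 1,
                 provenance = vector("list", n)),
            class = "residual_ensemble")
}

std_pop <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

# reference trajectory (computed once per test run)
ref_traj <- function() {
  cache_get("ref_traj", function() {
    simulate_clock(default_clock_params(), hours = 96, dt = 0.25)
  })
}

# small but complete synthetic study: panels from the default class specs
# plus in vivo expression under a known 2-feature transcription model
study_fixture <- function() {
  cache_get("study", function() {
    specs <- default_class_specs()
    bio <- lapply(specs, function(sp) {
      generate_biomarkers(sp, seed = 100 + sp$class_id)
    })
    grid <- common_grid()
    panels <- preprocess_panels(bio, grid = grid)
    truth <- ground_truth(
      "Bmal1", "H1", c("int_temperature", "food_intake"),
      beta = rbind(c(1, -0.7), c(1.2, -0.5), c(0.8, -0.9), c(1, -0.6)),
      noise_sd = 0.05)
    invivo <- generate_invivo_expression(truth, default_clock_params(),
                                         panels, seed = 7)
    xg <- preprocess_expression(invivo, "Bmal1", grid = grid)
    list(specs = specs, bio = bio, grid = grid, panels = panels,
         truth = truth, invivo = invivo, xg = xg)
  })
}

# moderate ensemble on the study fixture, shared across test files
study_ensemble <- function(n = 40, hypothesis = "H1") {
  key <- paste0("ens_", hypothesis, "_", n)
  cache_get(key, function() {
    fx <- study_fixture()
    spec <- perturbation_spec(sigma_eff = 0.1, n = n,
                              extra_coords = circlock:::default_perturb_set())
    generate_ensemble("Bmal1", hypothesis, fx$xg,
                      list(default_clock_params()), spec, fx$grid, seed = 11)
  })
}
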