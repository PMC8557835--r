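#' Configuration for an end-to-end pipeline run
#'
#' @param seed Top-level seed; per-stage seeds are derived as
#'   `(seed * 1000 + sum of the stage name's character codes) mod 2^31 - 1`.
#' @param class_specs List of 4 [class_spec()]s (default
#'   [default_class_specs()]).
#' @param truth A [ground_truth()] describing the generated regulation.
#' @param grid_n Common-grid size over one cycle (default 96, 15-min step).
#' @param n_traj Residual trajectories per class (demo default 50).
#' @param sigma_eff Relative perturbation sd under H3.
#' @param eps_scale Forcing excursion of the generator.
#' @param genes Genes to screen (default: the truth's target).
#' @param hypotheses Hypotheses to screen.
#' @param calibrate Run [fit_invitro()] (TRUE) or use the reference
#'   parameters as the single base set (FALSE, faster).
#' @param n_starts,n_best Calibration settings.
#' @param run_sobol Select perturbation coordinates via [sobol_select()]
#'   (TRUE) or use a fixed CLOCK/BMAL-loop set (FALSE, faster).
#' @param sobol_n Saltelli base sample size when `run_sobol`.
#' @param threshold Admissibility threshold on the total error E.
#' @param invitro_noise_sd Noise of the generated in vitro data.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            class_specs = default_class_specs(),
                            truth = ground_truth(
                              "Bmal1", "H1",
                              c("int_temperature", "food_intake"),
                              c(1, -0.7), noise_sd = 0.05),
                            grid_n = 96, n_traj = 50, sigma_eff = 0.1,
                            eps_scale = 0.3, genes = NULL,
                            hypotheses = c("H1", "H2"), calibrate = FALSE,
                            n_starts = 12, n_best = 10, run_sobol = FALSE,
                            sobol_n = 64, threshold = 0.15,
                            invitro_noise_sd = 0.02) {
  structure(list(seed = seed, class_specs = class_specs, truth = truth,
                 grid_n = grid_n, n_traj = n_traj, sigma_eff = sigma_eff,
                 eps_scale = eps_scale,
                 genes = genes %||% truth$target_gene,
                 hypotheses = hypotheses, calibrate = calibrate,
                 n_starts = n_starts, n_best = n_best,
                 run_sobol = run_sobol, sobol_n = sobol_n,
                 threshold = threshold,
                 invitro_noise_sd = invitro_noise_sd),
            class = "run_config")
}

stage_seed <- function(seed, stage) {
  (seed * 1000 + sum(utf8ToInt(stage))) %% (2^31 - 1)
}

# Sobol-selected perturbation coordinates of the reference model, all in the
# CLOCK/BMAL loop (used when the pipeline skips the Sobol stage)
default_perturb_set <- function() c("a_B", "a_K", "d_CB", "p_K", "p_B")

#' Smooth the raw biomarker tables of the four classes into panels
#'
#' @param biomarker_tables List of 4 long-format tables
#'   ([generate_biomarkers()] output).
#' @param grid Common grid (h).
#' @return List of 4 `regulator_panel`s.
#' @export
preprocess_panels <- function(biomarker_tables, grid = common_grid()) {
  lapply(seq_along(biomarker_tables), function(ci) {
    tab <- biomarker_tables[[ci]]
    sm <- lapply(split(tab, tab$biomarker), function(d) {
      fit_periodic_gp(d$time_h, d$value, grid = grid,
                      label = d$biomarker[1])
    })
    build_panel(sm[regulator_features()[1:5]], class_id = ci)
  })
}

#' Smooth in vivo expression of one gene into per-class mean profiles
#'
#' @param expr_table [generate_invivo_expression()] output.
#' @param gene Gene name.
#' @param grid Common grid (h).
#' @return List of 4 numeric vectors (one per class).
#' @export
preprocess_expression <- function(expr_table, gene, grid = common_grid()) {
  lapply(1:4, function(ci) {
    d <- expr_table[expr_table$gene == gene & expr_table$class == ci, ]
    if (nrow(d) == 0) stop("no expression data for gene ", gene,
                           " in class ", ci)
    fit_periodic_gp(d$time_h, d$value, grid = grid, label = gene)$mean
  })
}

#' Run the full pipeline
#'
#' Executes synth, preprocess, calibrate, residuals, search and class-stats
#' in order, writing stage outputs and a manifest (seeds, file hashes)
#' under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` keeps
#'   everything in memory.
#' @param verbose Print stage progress.
#' @return List with all stage results and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[circlock] ", ...)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  grid <- seq(0, 24, length.out = config$grid_n + 1)[seq_len(config$grid_n)]
  seeds <- vapply(c("synth", "calibrate", "sobol", "residuals", "search"),
                  function(s) stage_seed(config$seed, s), numeric(1))

  say("stage synth")
  bio <- lapply(config$class_specs, function(sp) {
    generate_biomarkers(sp, seed = seeds[["synth"]] + sp$class_id)
  })
  invitro <- generate_invitro_expression(default_clock_params(),
                                         noise_sd = config$invitro_noise_sd,
                                         seed = seeds[["synth"]])
  say("stage preprocess")
  panels <- preprocess_panels(bio, grid = grid)
  invivo <- generate_invivo_expression(config$truth, default_clock_params(),
                                       panels, seed = seeds[["synth"]],
                                       eps_scale = config$eps_scale)

  say("stage calibrate")
  base_sets <- if (config$calibrate) {
    fit_invitro(invitro, n_starts = config$n_starts,
                n_best = config$n_best, seed = seeds[["calibrate"]])
  } else {
    list(default_clock_params())
  }

  perturb_set <- if (config$run_sobol) {
    say("stage sobol")
    sobol_select(base_sets[[1]], n_sample = config$sobol_n,
                 seed = seeds[["sobol"]])$P
  } else {
    default_perturb_set()
  }

  say("stage residuals + search")
  screens <- list()
  shapleys <- list()
  ensembles <- list()
  for (g in config$genes) {
    xg <- preprocess_expression(invivo, g, grid = grid)
    for (h in config$hypotheses) {
      key <- paste(g, h, sep = ".")
      spec <- perturbation_spec(sigma_eff = config$sigma_eff,
                                n = config$n_traj,
                                extra_coords = perturb_set)
      ens <- generate_ensemble(g, h, xg, base_sets, spec, grid,
                               seed = seeds[["residuals"]] +
                                 sum(utf8ToInt(key)))
      ensembles[[key]] <- ens
      screens[[key]] <- screen_hypothesis(panels, ens,
                                          threshold = config$threshold)
      if (h == "H1") shapleys[[key]] <- shapley_table(panels, ens)
    }
  }

  say("stage class-stats")
  stats_out <- list()
  for (key in names(screens)) {
    sc <- screens[[key]]
    if (sc$verdict != "accepted") next
    res <- sc$all_models
    two <- res[res$size == 2, ]
    S <- attr(res, "subsets")[[two$enum_index[which.min(two$E)]]]
    w <- collect_weights(S, panels, ensembles[[key]])
    stats_out[[key]] <- list(best2 = S, anova = anova_weights(w),
                             constrained = constrained_refit(
                               S, panels, ensembles[[key]]))
  }

  manifest <- list(seed = config$seed, stage_seeds = as.list(seeds),
                   grid_n = config$grid_n, n_traj = config$n_traj,
                   perturb_set = perturb_set,
                   verdicts = lapply(screens, `[[`, "verdict"))
  result <- list(biomarkers = bio, invitro = invitro, invivo = invivo,
                 panels = panels, base_sets = base_sets,
                 ensembles = ensembles, screens = screens,
                 shapley = shapleys, class_stats = stats_out,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    for (ci in 1:4) {
      write_panel(panels[[ci]], file.path(out_dir,
                                          sprintf("panel_class%d.csv", ci)))
    }
    for (key in names(ensembles)) {
      write_ensemble(ensembles[[key]],
                     file.path(out_dir, sprintf("ensemble_%s.csv", key)))
    }
    utils::write.csv(invivo, file.path(out_dir, "invivo_expression.csv"),
                     row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    manifest$hashes <- as.list(tools::md5sum(files))
    names(manifest$hashes) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }
  result
}
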