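#' Pipeline run configuration
#'
#' @param midas Path to the training MIDAS file.
#' @param out_dir Output directory (created if needed).
#' @param truth_sif Optional reference-network SIF for topology scoring.
#' @param heldout_midas Optional held-out MIDAS file for prediction scoring
#'   (normalized by the training maxima).
#' @param max_indegree In-degree bound for DDN sampling.
#' @param n_models Ensemble size.
#' @param budget,local_budget Objective-evaluation budgets for global
#'   training and per-edge reduction refits.
#' @param polish,prefit_budget Quasi-Newton polish iterations and per-node
#'   teacher-forced pre-fit budget passed to [train_model()].
#' @param inhibitor_mode `"node"` or `"downstream"`.
#' @param inh_strength Strength applied to inhibitor flags.
#' @param seed Master seed; per-model seeds are derived deterministically
#'   from it so concurrent and sequential execution coincide.
#' @param stimuli Stimulus (source-only) node names; default: the MIDAS
#'   stimulus treatments.
#' @param reduce Run the greedy AIC reduction step (default `TRUE`).
#' @param bands Percentile bands for ensemble predictions.
#' @param rtol,atol Solver tolerances.
#' @return A `run_config` list.
#' @export
run_config <- function(midas, out_dir, truth_sif = NULL, heldout_midas = NULL,
                       max_indegree = 3, n_models = 10, budget = 6000,
                       local_budget = 1500, polish = 300, prefit_budget = 2000,
                       inhibitor_mode = c("node", "downstream"),
                       inh_strength = 0.9, seed = 1, stimuli = NULL,
                       reduce = TRUE, bands = c(20, 60, 95),
                       rtol = 1e-6, atol = 1e-8) {
  cfg <- list(midas = midas, out_dir = out_dir, truth_sif = truth_sif,
              heldout_midas = heldout_midas, max_indegree = max_indegree,
              n_models = n_models, budget = budget,
              local_budget = local_budget, polish = polish,
              prefit_budget = prefit_budget,
              inhibitor_mode = match.arg(inhibitor_mode),
              inh_strength = inh_strength, seed = seed, stimuli = stimuli,
              reduce = reduce, bands = bands, rtol = rtol, atol = atol)
  for (p in c("midas", "truth_sif", "heldout_midas")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      abort(paste0("config path does not exist: ", p, " = ", cfg[[p]]))
    }
  }
  if (cfg$n_models < 1) abort("n_models must be >= 1")
  structure(cfg, class = "run_config")
}

# Deterministic per-model seed below 2^31, independent of scheduling.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 7919 + i * 104729) %% 2147483647)
}

#' Run the five-step inference workflow end to end
#'
#' Executes, in order: (1) mutual-information matrix from the normalized
#' training data (inhibitor-adjusted when inhibitors are present); (2)
#' sampling of `n_models` bounded-in-degree data-driven networks; (3)
#' independent training of one logic-ODE model per network; (4) greedy AIC
#' reduction of each model; (5) ensemble median prediction. Artifacts
#' (model JSON documents, aggregate network, predictions, fit log, config
#' echo, evaluation report when references are supplied) are written under
#' `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `models`, `results`, `aggregate`,
#'   `predictions`, `evaluation` and `out_dir`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("[data] reading ", cfg$midas)
  pd <- normalize_dataset(read_midas(cfg$midas))
  jsonlite::write_json(as.list(pd$normalization),
                       file.path(cfg$out_dir, "normalization.json"),
                       auto_unbox = TRUE, digits = NA)

  say("[infer] mutual-information matrix")
  mim <- mi_matrix(pd)
  if (length(pd$inhibitors) > 0) {
    mim <- adjust_mi_for_inhibitors(pd, mim, cfg$inh_strength)
  }
  utils::write.csv(unclass(mim), file.path(cfg$out_dir, "mi_matrix.csv"))
  stimuli <- cfg$stimuli %||% intersect(pd$stimuli, rownames(mim))

  models <- list(); results <- list(); log_rows <- list()
  for (i in seq_len(cfg$n_models)) {
    seed_i <- derive_seed(cfg$seed, i)
    t0 <- proc.time()[["elapsed"]]
    net <- sample_ddn(mim, cfg$max_indegree, stimuli = stimuli, seed = seed_i)
    m <- logic_ode_model(net, observed = intersect(pd$signals, rownames(mim)),
                         inhibitor_mode = cfg$inhibitor_mode)
    fit <- train_model(m, pd, budget = cfg$budget, polish = cfg$polish,
                       prefit_budget = cfg$prefit_budget, seed = seed_i,
                       inh_strength = cfg$inh_strength,
                       rtol = cfg$rtol, atol = cfg$atol)
    say(sprintf("[train] model %d/%d: F = %.4g, AIC = %.4g", i,
                cfg$n_models, fit$objective, fit$aic))
    if (cfg$reduce) {
      red <- reduce_model(fit$model, fit, pd, local_budget = cfg$local_budget,
                          seed = seed_i)
      say(sprintf("[reduce] model %d: %d edge(s) removed, AIC = %.4g", i,
                  nrow(red$removed), red$result$aic))
      fit <- red$result
    }
    models[[i]] <- fit$model
    results[[i]] <- fit
    write_model_json(fit$model,
                     file.path(cfg$out_dir, sprintf("model_%03d.json", i)))
    log_rows[[i]] <- tibble(
      model = i, seed = seed_i, F = fit$objective, K = fit$K, aic = fit$aic,
      n_edges = nrow(model_edges(fit$model)),
      wall_s = proc.time()[["elapsed"]] - t0
    )
  }
  log <- dplyr::bind_rows(log_rows)
  readr::write_csv(log, file.path(cfg$out_dir, "fit_log.csv"))

  agg <- aggregate_network(models)
  write_sif(agg, file.path(cfg$out_dir, "aggregate_network.sif"))
  readr::write_csv(as_tibble(agg), file.path(cfg$out_dir,
                                             "aggregate_network.csv"))

  say("[predict] ensemble predictions")
  pred_pd <- if (!is.null(cfg$heldout_midas)) {
    normalize_dataset(read_midas(cfg$heldout_midas), maxima = pd$normalization)
  } else pd
  exps <- setNames(lapply(experiment_ids(pred_pd), get_experiment,
                          x = pred_pd), experiment_ids(pred_pd))
  times <- sort(unique(pred_pd$measurements$time))
  pred <- ensemble_predict(models, exps, times, bands = cfg$bands,
                           inh_strength = cfg$inh_strength,
                           rtol = cfg$rtol, atol = cfg$atol)
  readr::write_csv(as_tibble(pred), file.path(cfg$out_dir, "predictions.csv"))

  evaluation <- list()
  evaluation$rmse <- rmse(pred, pred_pd)
  if (!is.null(cfg$truth_sif)) {
    truth <- read_sif(cfg$truth_sif, nodes = rownames(mim), stimuli = stimuli)
    pr <- pr_analysis(agg, truth)
    evaluation$aupr <- pr$aupr
    readr::write_csv(pr$curve, file.path(cfg$out_dir, "pr_curve.csv"))
  }
  jsonlite::write_json(evaluation, file.path(cfg$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_echo <- unclass(cfg)
  jsonlite::write_json(cfg_echo, file.path(cfg$out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("[done] artifacts in ", cfg$out_dir)
  invisible(list(models = models, results = results, aggregate = agg,
                 predictions = pred, evaluation = evaluation,
                 out_dir = cfg$out_dir))
}
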