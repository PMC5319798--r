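#' Ensemble trajectory prediction
#'
#' Simulates every member model for each experiment and combines them
#' per (time, signal) into the ensemble median plus empirical central
#' percentile bands (linear interpolation between order statistics; even
#' member counts use the midpoint median). Members whose integration fails
#' are dropped from that experiment only, and the dropped count is recorded.
#'
#' @param models List of `logic_ode_model`s sharing a node namespace.
#' @param experiments A single experiment (list with `stimuli`, `inhibitors`)
#'   or a named list of them; experiments extracted with [get_experiment()]
#'   work directly.
#' @param times Sampling instants.
#' @param bands Central interval widths in percent (default 20, 60, 95).
#' @param inh_strength,rtol,atol Passed to the simulator.
#' @param signals Signals to report; default the union of the models'
#'   observed sets.
#' @return An `ensemble_prediction` tibble: `experiment`, `time`, `signal`,
#'   `median`, and `lower_<band>` / `upper_<band>` columns, with attributes
#'   `n_models` and `n_failed` (per experiment).
#' @export
ensemble_predict <- function(models, experiments, times, bands = c(20, 60, 95),
                             inh_strength = 0.9, rtol = 1e-6, atol = 1e-8,
                             signals = NULL) {
  if (length(models) < 1) abort("need at least one model")
  if (any(bands <= 0 | bands >= 100)) abort("band widths must lie in (0, 100)")
  single <- length(experiments) == 0 ||
    any(c("stimuli", "inhibitors", "times", "values") %in% names(experiments))
  if (single) experiments <- list(experiment = experiments)
  if (is.null(names(experiments))) {
    names(experiments) <- paste0("experiment_", seq_along(experiments))
  }
  signals <- signals %||% Reduce(union, lapply(models, `[[`, "observed"))
  bands <- sort(bands)
  n_failed <- integer(0)
  out <- purrr::map_dfr(names(experiments), function(id) {
    ex <- experiments[[id]]
    sims <- lapply(models, function(m) {
      tryCatch(sim_matrix(m, ex, times, inh_strength = inh_strength,
                          rtol = rtol, atol = atol),
               error = function(e) NULL)
    })
    failed <- sum(vapply(sims, is.null, logical(1)))
    n_failed[[id]] <<- failed
    sims <- sims[!vapply(sims, is.null, logical(1))]
    if (length(sims) == 0) {
      abort(paste0("all ensemble members failed on experiment ", id))
    }
    if (failed > 0) {
      warn(paste0(failed, " ensemble member(s) dropped on experiment ", id))
    }
    # array members x time x signal
    arr <- vapply(sims, function(s) s[, signals, drop = FALSE],
                  matrix(0, length(times), length(signals)))
    if (length(times) == 1 || length(signals) == 1) {
      dim(arr) <- c(length(times), length(signals), length(sims))
    }
    purrr::map_dfr(seq_along(signals), function(jj) {
      vals <- arr[, jj, , drop = FALSE]
      dim(vals) <- c(length(times), length(sims))
      row <- tibble(experiment = id, time = times, signal = signals[jj],
                    median = apply(vals, 1, median))
      for (b in bands) {
        p <- c((100 - b) / 200, 1 - (100 - b) / 200)
        q <- apply(vals, 1, quantile, probs = p, names = FALSE, type = 7)
        row[[paste0("lower_", b)]] <- q[1, ]
        row[[paste0("upper_", b)]] <- q[2, ]
      }
      row
    })
  })
  structure(out, class = c("ensemble_prediction", class(tibble())),
            n_models = length(models), n_failed = n_failed, bands = bands)
}

#' Aggregate network of an ensemble
#'
#' Edge confidence is the fraction of member models whose active edge set
#' contains the edge; the result ranks candidate interactions for
#' precision-recall evaluation.
#'
#' @param models List of `logic_ode_model`s.
#' @return Tibble `from`, `to`, `confidence` (only edges with confidence > 0)
#'   with a `nodes` attribute; convert with [as_adjacency()].
#' @export
aggregate_network <- function(models) {
  if (length(models) < 1) abort("need at least one model")
  nodes <- Reduce(union, lapply(models, `[[`, "nodes"))
  counts <- purrr::map_dfr(models, model_edges) |>
    dplyr::count(.data$from, .data$to, name = "n_models") |>
    dplyr::mutate(confidence = .data$n_models / length(models)) |>
    dplyr::select("from", "to", "confidence") |>
    dplyr::arrange(dplyr::desc(.data$confidence), .data$from, .data$to)
  structure(counts, nodes = nodes,
            class = c("edge_confidence", class(tibble())))
}

#' Ensemble skill as a function of ensemble size
#'
#' For each candidate size, draws `n_resamples` random member subsets
#' (without replacement) and averages a user metric of the sub-ensemble;
#' used to check that predictive skill has converged in the ensemble size.
#'
#' @param models List of member models.
#' @param metric Function `(models) -> scalar` (e.g. ensemble RMSE on a
#'   held-out design).
#' @param sizes Ensemble sizes to probe (each \eqn{\le} `length(models)`).
#' @param n_resamples Random subsets per size.
#' @param seed Optional integer seed.
#' @return Tibble `size`, `mean_metric`.
#' @export
bootstrap_ensemble_curve <- function(models, metric, sizes,
                                     n_resamples = 10, seed = NULL) {
  if (any(sizes > length(models))) {
    abort("sizes cannot exceed the number of available models")
  }
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(sizes, function(sz) {
    vals <- vapply(seq_len(n_resamples), function(r) {
      metric(models[sample.int(length(models), sz)])
    }, numeric(1))
    tibble(size = sz, mean_metric = mean(vals))
  })
}

#' @export
autoplot.ensemble_prediction <- function(object, ...) {
  bands <- attr(object, "bands")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time))
  for (b in rev(sort(bands))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[paste0("lower_", b)]],
                   ymax = .data[[paste0("upper_", b)]]),
      fill = "firebrick", alpha = 0.18)
  }
  p + ggplot2::geom_line(ggplot2::aes(y = .data$median), color = "firebrick") +
    ggplot2::facet_grid(signal ~ experiment, scales = "free_y") +
    ggplot2::labs(x = "time", y = "normalized activity",
                  title = "Ensemble prediction (median with central bands)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mi_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to, fill = .data$mi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "MI (bits)") +
    ggplot2::labs(x = NULL, y = NULL, title = "Mutual information") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.training_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$eval, .data$best_F)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "objective evaluations", y = "best F",
                  title = "Training convergence") +
    ggplot2::theme_minimal()
}
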