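#' Root mean square error of trajectory predictions
#'
#' Pools squared residuals over every experiment, observed signal and
#' sampling point, divides by the pooled residual count, and takes the square
#' root. Missing observations are skipped.
#'
#' @param pred Prediction table: tibble with `experiment`, `time`, `signal`
#'   and either `value` or `median` (an [ensemble_predict()] result works
#'   directly).
#' @param obs A [perturbation_data] with the observations.
#' @return The scalar RMSE (normalized signal units).
#' @export
rmse <- function(pred, obs) {
  stopifnot(inherits(obs, "perturbation_data"))
  pred <- as_tibble(pred)
  vcol <- if ("value" %in% names(pred)) "value" else "median"
  if (!vcol %in% names(pred)) abort("pred needs a value or median column")
  j <- dplyr::inner_join(
    dplyr::select(pred, "experiment", "time", "signal", pred_value = !!vcol),
    dplyr::filter(obs$measurements, !is.na(.data$value)),
    by = c("experiment", "time", "signal")
  )
  if (nrow(j) == 0) abort("no overlapping (experiment, time, signal) points")
  sqrt(sum((j$value - j$pred_value)^2) / nrow(j))
}

# Candidate edge table: every ordered pair (no self-loops) over the node set,
# with its score (0 when unscored) and truth label.
candidate_edges <- function(scores, truth, nodes = NULL, symmetrize = FALSE) {
  sc <- if (is.matrix(scores)) {
    as_tibble(as.data.frame(as.table(scores))) |>
      setNames(c("from", "to", "confidence")) |>
      dplyr::mutate(from = as.character(.data$from), to = as.character(.data$to))
  } else as_tibble(scores)
  tr <- as_tibble(truth)[c("from", "to")]
  if (symmetrize) {
    sc <- dplyr::bind_rows(sc, dplyr::rename(sc, from = "to", to = "from")) |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(confidence = max(.data$confidence), .groups = "drop")
  }
  nodes <- nodes %||% attr(truth, "nodes") %||%
    unique(c(sc$from, sc$to, tr$from, tr$to))
  from <- rep(nodes, each = length(nodes))
  to <- rep(nodes, times = length(nodes))
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  key <- paste(from, to)
  conf <- sc$confidence[match(key, paste(sc$from, sc$to))]
  conf[is.na(conf)] <- 0
  tibble(from = from, to = to, confidence = conf,
         truth = key %in% paste(tr$from, tr$to))
}

# Shared threshold sweep: one row per distinct score (descending), ties
# grouped at a single threshold.
threshold_sweep <- function(cand) {
  o <- order(cand$confidence, decreasing = TRUE)
  conf <- cand$confidence[o]; lab <- cand$truth[o]
  P <- sum(lab); Nn <- sum(!lab)
  ctp <- cumsum(lab); cfp <- cumsum(!lab)
  last <- !duplicated(conf, fromLast = TRUE)  # last row of each tie group
  tp <- ctp[last]; fp <- cfp[last]
  tibble(threshold = conf[last], tp = tp, fp = fp, fn = P - tp, tn = Nn - fp,
         precision = ifelse(tp + fp > 0, tp / (tp + fp), 1),
         recall = if (P > 0) tp / P else rep(0, length(tp)),
         fpr = if (Nn > 0) fp / Nn else rep(0, length(fp)))
}

#' Precision-recall analysis of ranked edge confidences
#'
#' Sweeps every distinct confidence value as a threshold (ties grouped) over
#' all directed candidate edges (self-loops excluded) and scores the ranking
#' against a reference network. The area under the precision-recall curve is
#' accumulated step-wise: each increment in recall contributes that
#' threshold's precision, with no interpolation. An edge predicted in the
#' wrong direction counts as a false positive.
#'
#' @param scores Edge confidences: tibble `from`, `to`, `confidence` (e.g.
#'   from [aggregate_network()]) or a square adjacency-style matrix.
#' @param truth Reference network: a [network()] or an edge tibble; must
#'   contain at least one edge.
#' @param nodes Candidate node set; defaults to the truth network's nodes.
#' @param symmetrize Score each undirected pair with the max of the two
#'   directions before evaluation (for comparing undirected methods).
#' @return A `pr_result`: list with `curve` (tibble `threshold`, `tp`, `fp`,
#'   `fn`, `tn`, `precision`, `recall`) and `aupr`.
#' @export
pr_analysis <- function(scores, truth, nodes = NULL, symmetrize = FALSE) {
  cand <- candidate_edges(scores, truth, nodes, symmetrize)
  if (sum(cand$truth) == 0) abort("truth network has no positive edges")
  curve <- threshold_sweep(cand)
  rec <- c(0, curve$recall)
  aupr <- sum(curve$precision * diff(rec))
  structure(list(curve = curve, aupr = aupr), class = "pr_result")
}

#' ROC analysis of ranked edge confidences
#'
#' Standard ROC sweep over all directed candidate edges with ties grouped at
#' one threshold; the area under the curve is computed by the trapezoid rule
#' between (0, 0) and (1, 1).
#'
#' @inheritParams pr_analysis
#' @return A `roc_result`: list with `curve` (tibble including `fpr` and
#'   `recall`) and `auroc`.
#' @export
roc_analysis <- function(scores, truth, nodes = NULL, symmetrize = FALSE) {
  cand <- candidate_edges(scores, truth, nodes, symmetrize)
  if (sum(cand$truth) == 0 || sum(!cand$truth) == 0) {
    abort("ROC needs at least one positive and one negative edge")
  }
  curve <- threshold_sweep(cand)
  x <- c(0, curve$fpr, 1)
  y <- c(0, curve$recall, 1)
  auroc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  structure(list(curve = curve, auroc = auroc), class = "roc_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat("<pr_result> AUPR = ", signif(x$aupr, 4), " over ",
      nrow(x$curve), " thresholds\n", sep = "")
  invisible(x)
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUROC = ", signif(x$auroc, 4), " over ",
      nrow(x$curve), " thresholds\n", sep = "")
  invisible(x)
}

#' @export
tidy.pr_result <- function(x, ...) x$curve

#' @export
glance.pr_result <- function(x, ...) tibble(aupr = x$aupr)

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) tibble(auroc = x$auroc)

#' @export
autoplot.pr_result <- function(object, ...) {
  df <- dplyr::bind_rows(object$curve,
                         tibble(recall = 0, precision = object$curve$precision[1]))
  ggplot2::ggplot(df, ggplot2::aes(.data$recall, .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = paste0("Precision-recall (AUPR = ",
                                 signif(object$aupr, 3), ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tibble(fpr = c(0, object$curve$fpr, 1),
               recall = c(0, object$curve$recall, 1))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$recall)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = 2, color = "grey60") +
    ggplot2::labs(title = paste0("ROC (AUROC = ", signif(object$auroc, 3), ")"),
                  x = "false positive rate", y = "recall") +
    ggplot2::theme_minimal()
}
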