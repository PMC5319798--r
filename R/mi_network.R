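#' Pooled signal matrix used for mutual-information estimation
#'
#' Samples are pooled across all experiments and time points; stimulus
#' treatments can be included as pseudo-signals (their level replicated across
#' an experiment's time points) so ligand nodes can act as candidate parents.
#'
#' @noRd
pooled_matrix <- function(x, include_stimuli = TRUE) {
  wide <- x$measurements |>
    tidyr::pivot_wider(names_from = "signal", values_from = "value") |>
    dplyr::arrange(.data$experiment, .data$time)
  stim_names <- setdiff(x$stimuli, x$signals)
  if (include_stimuli && length(stim_names) > 0) {
    st <- x$treatments |>
      dplyr::filter(.data$type == "stimulus", .data$name %in% stim_names) |>
      tidyr::pivot_wider(names_from = "name", values_from = "level",
                         id_cols = "experiment", values_fill = 0)
    wide <- dplyr::left_join(wide, st, by = "experiment")
  }
  keep <- c(intersect(x$signals, names(wide)),
            if (include_stimuli) intersect(stim_names, names(wide)))
  m <- as.matrix(wide[keep])
  storage.mode(m) <- "double"
  m
}

discretize_column <- function(v, n_bins, method) {
  ok <- !is.na(v)
  out <- rep(NA_integer_, length(v))
  u <- unique(v[ok])
  if (length(u) <= 1) { out[ok] <- 1L; return(out) }
  breaks <- if (method == "equalwidth") {
    seq(min(v[ok]), max(v[ok]), length.out = n_bins + 1)
  } else {
    unique(quantile(v[ok], probs = seq(0, 1, length.out = n_bins + 1),
                    names = FALSE, type = 7))
  }
  if (length(breaks) < 2) { out[ok] <- 1L; return(out) }
  out[ok] <- as.integer(cut(v[ok], breaks = breaks, include.lowest = TRUE))
  out
}

# Plug-in (empirical) mutual information of two discretized columns, in the
# requested log base, over pairwise-complete samples.
plugin_mi <- function(bi, bj, base = 2) {
  ok <- !is.na(bi) & !is.na(bj)
  if (sum(ok) < 2) return(0)
  tab <- table(bi[ok], bj[ok])
  p <- tab / sum(tab)
  pi_ <- rowSums(p); pj <- colSums(p)
  ind <- outer(pi_, pj)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / ind[nz])) / log(base)
}

#' Estimate the mutual-information matrix of a perturbation dataset
#'
#' Computes the empirical (plug-in) mutual information, in bits, between every
#' pair of measured variables after discretization. Samples are pooled across
#' all experiments and time points; missing values are excluded pairwise.
#' The diagonal holds each variable's binned entropy.
#'
#' @param x A [perturbation_data] object.
#' @param n_bins Number of discretization bins; default
#'   \eqn{\lceil\sqrt{N}\rceil} with \eqn{N} the pooled sample count.
#' @param method Discretization: `"equalfreq"` (default) or `"equalwidth"`.
#' @param include_stimuli Include stimulus treatments as pseudo-signals
#'   (default `TRUE`), so ligands can be sampled as network parents.
#' @param base Logarithm base (2 = bits, the default).
#' @return An object of class `mi_matrix`: the symmetric non-negative MI
#'   matrix with `signal_names` attribute.
#' @export
mi_matrix <- function(x, n_bins = NULL, method = c("equalfreq", "equalwidth"),
                      include_stimuli = TRUE, base = 2) {
  stopifnot(inherits(x, "perturbation_data"))
  method <- match.arg(method)
  m <- pooled_matrix(x, include_stimuli)
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing)) {
    abort(paste0("signal entirely missing: ", toString(colnames(m)[all_missing])))
  }
  if (nrow(m) < 2) abort("need at least 2 pooled samples per signal")
  if (is.null(n_bins)) n_bins <- ceiling(sqrt(nrow(m)))
  disc <- apply(m, 2, discretize_column, n_bins = n_bins, method = method)
  p <- ncol(m)
  mim <- matrix(0, p, p, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p)) {
    for (j in i:p) {
      mim[i, j] <- mim[j, i] <- plugin_mi(disc[, i], disc[, j], base = base)
    }
  }
  new_mi_matrix(mim, n_bins = n_bins, method = method, base = base)
}

new_mi_matrix <- function(values, ...) {
  structure(values, class = c("mi_matrix", "matrix", "array"),
            mi_settings = list(...))
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat("<mi_matrix> ", nrow(x), "x", ncol(x), " (bits)\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' @export
tidy.mi_matrix <- function(x, ...) {
  as_tibble(as.data.frame(as.table(unclass(x))), .name_repair = "minimal") |>
    setNames(c("from", "to", "mi")) |>
    dplyr::mutate(from = as.character(.data$from), to = as.character(.data$to))
}

#' Inhibitor-adjusted mutual-information matrix
#'
#' Inhibitors may mask a regulator's influence in the raw data. This
#' adjustment computes a second MI matrix on data where inhibited species are
#' scaled by \eqn{(1-\mathrm{inh})} in the conditions where their inhibitor
#' was applied, and returns the elementwise maximum of the scaled-data MI and
#' the raw MI. With no inhibitors in the dataset the raw matrix is returned
#' unchanged.
#'
#' @param x A [perturbation_data] object.
#' @param raw The raw [mi_matrix()] of `x` (same settings are reused).
#' @param inh_strength Inhibition strength in \eqn{[0,1]} used for the
#'   scaling; default 0.9.
#' @return An `mi_matrix` of the same shape as `raw`.
#' @export
adjust_mi_for_inhibitors <- function(x, raw, inh_strength = 0.9) {
  stopifnot(inherits(x, "perturbation_data"), inherits(raw, "mi_matrix"))
  if (inh_strength < 0 || inh_strength > 1) {
    abort("inh_strength must lie in [0, 1]")
  }
  inh_tab <- dplyr::filter(x$treatments, .data$type == "inhibitor",
                           .data$level > 0)
  if (nrow(inh_tab) == 0 || length(x$inhibitors) == 0) return(raw)
  st <- attr(raw, "mi_settings")
  scaled <- x
  key <- paste(inh_tab$experiment, inh_tab$name)
  hit <- paste(scaled$measurements$experiment, scaled$measurements$signal) %in% key
  scaled$measurements$value[hit] <- scaled$measurements$value[hit] *
    (1 - inh_strength)
  mi_s <- mi_matrix(scaled, n_bins = st$n_bins, method = st$method,
                    include_stimuli = TRUE, base = st$base)
  common <- rownames(raw)
  out <- pmax(unclass(raw), unclass(mi_s)[common, common])
  new_mi_matrix(out, n_bins = st$n_bins, method = st$method, base = st$base)
}

#' Directed networks with bounded in-degree
#'
#' @param edges Tibble (or data frame) with columns `from`, `to`.
#' @param nodes Character vector of all node names (defaults to those present
#'   in `edges`).
#' @param stimuli Nodes that are experimentally controlled inputs; they must
#'   have in-degree 0.
#' @return A `ddn_network`: a tibble of edges with `nodes` and `stimuli`
#'   attributes.
#' @export
network <- function(edges, nodes = NULL, stimuli = character()) {
  edges <- as_tibble(edges)
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges))) {
    abort("edges must have columns from, to")
  }
  if (nrow(edges) == 0) edges <- tibble(from = character(), to = character())
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    abort("edges reference nodes outside the node set")
  }
  if (any(edges$from == edges$to)) abort("self-loops are not allowed")
  if (any(edges$to %in% stimuli)) abort("stimulus nodes cannot have parents")
  if (anyDuplicated(paste(edges$from, edges$to))) abort("duplicate edges")
  structure(dplyr::arrange(edges, match(.data$to, nodes), match(.data$from, nodes)),
            nodes = nodes, stimuli = stimuli,
            class = c("ddn_network", class(tibble())))
}

#' @export
print.ddn_network <- function(x, ...) {
  cat("<ddn_network> ", length(attr(x, "nodes")), " nodes, ", nrow(x),
      " edges; stimuli: ", toString(attr(x, "stimuli")), "\n", sep = "")
  NextMethod()
}

#' Sample a data-driven network from a mutual-information matrix
#'
#' For every non-stimulus target node, up to `max_indegree` distinct parents
#' are drawn without replacement, each candidate with probability proportional
#' to its mutual information with the target. Zero-MI candidates are never
#' selected; stimulus nodes receive no parents; self-loops are excluded.
#'
#' @param mim An [mi_matrix()].
#' @param max_indegree In-degree bound: a single number or a named vector per
#'   node.
#' @param stimuli Character vector of stimulus (source-only) nodes.
#' @param seed Optional integer seed for reproducible sampling.
#' @return A [network()] whose per-node in-degree respects the bound.
#' @export
sample_ddn <- function(mim, max_indegree, stimuli = character(), seed = NULL) {
  stopifnot(inherits(mim, "mi_matrix"))
  nodes <- rownames(mim)
  if (!is.null(seed)) set.seed(seed)
  bound <- if (length(max_indegree) == 1) {
    setNames(rep(max_indegree, length(nodes)), nodes)
  } else max_indegree[nodes]
  if (any(is.na(bound)) || any(bound[!nodes %in% stimuli] < 1)) {
    abort("max_indegree must be >= 1 for every non-stimulus node")
  }
  edges <- purrr::map_dfr(setdiff(nodes, stimuli), function(tg) {
    cand <- setdiff(nodes, tg)
    w <- unclass(mim)[cand, tg]
    cand <- cand[w > 0]; w <- w[w > 0]
    if (length(cand) == 0) {
      warn(paste0("no positive-MI candidates for node ", tg,
                  "; left parentless"))
      return(tibble(from = character(), to = character()))
    }
    k <- min(bound[tg], length(cand))
    sel <- if (length(cand) == 1) cand else sample(cand, k, prob = w)
    tibble(from = sel, to = tg)
  })
  network(edges, nodes = nodes, stimuli = stimuli)
}

#' Read / write networks in SIF format
#'
#' SIF rows are `source <tab> interaction <tab> target`; the interaction tag
#' is written as `1` and ignored on read.
#'
#' @param path File path.
#' @param nodes,stimuli Passed to [network()] on read.
#' @return [read_sif()] returns a `ddn_network`; [write_sif()] returns `path`
#'   invisibly.
#' @export
read_sif <- function(path, nodes = NULL, stimuli = character()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) == 0) return(network(tibble(), nodes = nodes %||% character(),
                                       stimuli = stimuli))
  parts <- strsplit(txt, "\t| +")
  edges <- tibble(from = purrr::map_chr(parts, 1),
                  to = purrr::map_chr(parts, ~ .x[[length(.x)]]))
  network(edges, nodes = nodes, stimuli = stimuli)
}

#' @rdname read_sif
#' @param x A `ddn_network` or an edge tibble with optional `confidence`.
#' @export
write_sif <- function(x, path) {
  lines <- if (nrow(x) == 0) character() else {
    tag <- if ("confidence" %in% names(x)) format(x$confidence) else "1"
    paste(x$from, tag, x$to, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Adjacency-matrix view of a network or edge-confidence table
#'
#' @param x A `ddn_network` or a tibble with `from`, `to` and optionally
#'   `confidence` columns.
#' @param nodes Node ordering (defaults to the network's node attribute).
#' @return A numeric matrix A with `A[i, j] = 1` (or the confidence) when the
#'   edge i -> j is present.
#' @export
as_adjacency <- function(x, nodes = NULL) {
  nodes <- nodes %||% attr(x, "nodes") %||% unique(c(x$from, x$to))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(x) > 0) {
    v <- if ("confidence" %in% names(x)) x$confidence else 1
    A[cbind(match(x$from, nodes), match(x$to, nodes))] <- v
  }
  A
}

`%||%` <- function(a, b) if (is.null(a)) b else a
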