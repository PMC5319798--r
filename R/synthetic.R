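#' Configuration of a synthetic signaling benchmark
#'
#' Describes a ground-truth generator emulating the study conditions of
#' typical perturbation screens: a bounded-in-degree directed scaffold rooted
#' at ligand (stimulus) nodes, logic-ODE dynamics on \eqn{[0,1]}, full-cross
#' ligand on/off (or off/low/high) designs combined with one-at-a-time node
#' inhibition, additive Gaussian measurement noise with \eqn{\sigma = 0.05},
#' and per-signal max normalization downstream.
#'
#' @param n_nodes Total node count (stimuli included).
#' @param n_stimuli Number of ligand nodes (< `n_nodes`).
#' @param max_indegree In-degree bound of the scaffold.
#' @param noise_sd Gaussian measurement noise sd in normalized units
#'   (default 0.05).
#' @param times Sampling grid (data time units).
#' @param inhibitor_mode `"node"` or `"downstream"`, used both for the truth
#'   dynamics and by models fit to the data.
#' @param inh_strength Inhibition strength applied when an inhibitor flag is
#'   on (default 0.9).
#' @param ligand_levels Levels each ligand can take (default on/off
#'   `c(0, 1)`; use `c(0, 0.5, 1)` for off/low/high).
#' @param observed Optional subset of nodes reported as measured signals
#'   (default: all nodes except pure ligands, which enter as treatments).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_nodes = 6, n_stimuli = 2, max_indegree = 2,
                             noise_sd = 0.05, times = c(0, 1, 2, 4, 7, 10),
                             inhibitor_mode = c("node", "downstream"),
                             inh_strength = 0.9, ligand_levels = c(0, 1),
                             observed = NULL) {
  if (n_stimuli >= n_nodes) abort("n_stimuli must be smaller than n_nodes")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  structure(
    list(n_nodes = n_nodes, n_stimuli = n_stimuli, max_indegree = max_indegree,
         noise_sd = noise_sd, times = times,
         inhibitor_mode = match.arg(inhibitor_mode),
         inh_strength = inh_strength, ligand_levels = ligand_levels,
         observed = observed),
    class = "synthetic_config"
  )
}

#' Generate a ground-truth logic-ODE model and its network
#'
#' Builds an acyclic scaffold: nodes are ordered with the ligands first;
#' every non-stimulus node is regulated by the node immediately preceding it
#' (a connected cascade, a chain when `max_indegree = 1`) plus 0 to
#' `max_indegree - 1` further parents drawn from the remaining upstream
#' nodes, so the first species is ligand-driven and signal flows downstream. Each node realizes a named Boolean gate chosen at
#' random — single activator, NOT (inhibitory), AND, OR — through 0/1 corner
#' weights, with Hill and lifetime parameters drawn from moderate ranges well
#' inside the default training bounds.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Optional integer seed.
#' @return List with `model` (a `logic_ode_model`) and `network` (the truth
#'   scaffold).
#' @export
generate_truth_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  n_spec <- cfg$n_nodes - cfg$n_stimuli
  if (cfg$max_indegree < 1) abort("max_indegree must be >= 1")
  stimuli <- paste0("L", seq_len(cfg$n_stimuli))
  species <- paste0("X", seq_len(n_spec))
  nodes <- c(stimuli, species)
  # backbone: each species' first parent is the immediately preceding node,
  # so the scaffold is a connected cascade (a chain when max_indegree = 1);
  # any further parents are drawn from the remaining upstream nodes
  edges <- purrr::map_dfr(seq_along(species), function(i) {
    pool <- nodes[seq_len(cfg$n_stimuli + i - 1)]
    backbone <- pool[length(pool)]
    rest <- setdiff(pool, backbone)
    k_extra <- sample.int(min(cfg$max_indegree, length(pool)), 1) - 1L
    extra <- if (k_extra > 0 && length(rest) > 0)
      sample(rest, min(k_extra, length(rest))) else character()
    tibble(from = c(backbone, extra), to = species[i])
  })
  net <- network(edges, nodes = nodes, stimuli = stimuli)
  m <- logic_ode_model(net, observed = cfg$observed %||% species,
                       inhibitor_mode = cfg$inhibitor_mode)
  for (v in species) {
    N <- length(m$regulators[[v]])
    gate <- if (N == 1) sample(c("act", "not"), 1, prob = c(0.8, 0.2)) else
      sample(c("and", "or"), 1)
    lbl <- corner_labels(N)
    on_count <- vapply(seq_len(2^N) - 1L, function(j)
      sum(vapply(seq_len(N), function(kk)
        bitwAnd(bitwShiftR(j, kk - 1L), 1L), integer(1))), integer(1))
    wv <- switch(gate,
      act = c(0, 1),
      not = c(1, 0),
      and = as.numeric(on_count == N),
      or = as.numeric(on_count > 0))
    m$weights[[v]] <- setNames(wv, lbl)
    m$hill_n[[v]][] <- runif(N, 1.5, 4)
    m$hill_k[[v]][] <- runif(N, 0.3, 0.7)
    m$tau[[v]] <- runif(1, 0.5, 3)
  }
  list(model = validate_model(m), network = net)
}

#' Generate a stimulus x inhibition experimental design
#'
#' Crosses every combination of ligand levels with single-node inhibitions:
#' each inhibitable signal is inhibited one at a time, optionally alongside
#' an uninhibited control arm. The experiment count is therefore
#' \eqn{\prod_\ell |\mathrm{levels}_\ell| \times (|\mathrm{inhibitable}| + 1)}
#' with the control, or \eqn{\times |\mathrm{inhibitable}|} without it.
#'
#' @param observed Character vector of measured signals (defines the design's
#'   signal universe).
#' @param ligands Ligand names (subset of the node namespace, disjoint from
#'   `inhibitable`).
#' @param levels Levels per ligand: a numeric vector applied to all ligands,
#'   or a named list per ligand.
#' @param inhibitable Signals that can be inhibited one at a time.
#' @param include_control Include the no-inhibitor arm (default `TRUE`).
#' @return Tibble with `experiment` ids and list-columns `stimuli`,
#'   `inhibitors` (named numeric vectors; inhibitor entries are 0/1 applied
#'   flags).
#' @export
generate_design <- function(observed, ligands, levels = c(0, 1),
                            inhibitable = character(),
                            include_control = TRUE) {
  if (length(observed) == 0) abort("observed signal list is empty")
  if (any(inhibitable %in% ligands)) {
    abort("inhibitable signals must be disjoint from ligands")
  }
  lev_list <- if (is.list(levels)) levels[ligands] else
    setNames(rep(list(levels), length(ligands)), ligands)
  grid <- expand.grid(lev_list, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) grid <- data.frame(row.names = 1)
  arms <- c(if (include_control) list(character(0)),
            lapply(inhibitable, identity))
  if (length(arms) == 0) abort("design has no arms: no control and nothing inhibitable")
  purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    stim <- if (length(ligands)) setNames(as.numeric(unlist(grid[g, ])), ligands) else
      setNames(numeric(), character())
    purrr::map_dfr(arms, function(inh) {
      id <- paste0(
        if (length(ligands)) paste(paste0(ligands, "=", stim), collapse = "|")
        else "control",
        if (length(inh)) paste0("|", inh, "i") else "")
      tibble(experiment = id, stimuli = list(stim),
             inhibitors = list(if (length(inh)) setNames(1, inh) else
               setNames(numeric(), character())))
    })
  })
}

#' Simulate a (noisy) dataset from a truth model under a design
#'
#' Simulates every experiment of the design from the model's resting initial
#' state, samples at the configured times, restricts to the observed signals,
#' adds iid Gaussian noise of sd `cfg$noise_sd`, and clips to \eqn{[0, 1]}
#' (so downstream normalization and the logic-ODE range assumption hold).
#' `noise_sd = 0` returns the noise-free simulation exactly.
#'
#' @param model A truth `logic_ode_model`.
#' @param design A design tibble from [generate_design()].
#' @param cfg The [synthetic_config()] (times, noise, inhibition strength,
#'   observation mask).
#' @param seed Optional integer seed for the noise.
#' @return A [perturbation_data] with the ligands as stimulus treatments and
#'   the one-at-a-time inhibitions as inhibitor flags.
#' @export
simulate_dataset <- function(model, design, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  observed <- cfg$observed %||% model$observed
  if (!all(observed %in% model$nodes)) abort("observed signals outside model")
  meas <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    ex <- list(stimuli = design$stimuli[[i]], inhibitors = design$inhibitors[[i]],
               id = design$experiment[i])
    tr <- sim_matrix(model, ex, cfg$times, inh_strength = cfg$inh_strength)
    vals <- as.vector(tr[, observed, drop = FALSE])
    if (cfg$noise_sd > 0) {
      vals <- pmin(pmax(vals + rnorm(length(vals), 0, cfg$noise_sd), 0), 1)
    }
    tibble(experiment = design$experiment[i],
           time = rep(cfg$times, times = length(observed)),
           signal = rep(observed, each = length(cfg$times)),
           value = vals)
  })
  treat <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    st <- design$stimuli[[i]]; inh <- design$inhibitors[[i]]
    dplyr::bind_rows(
      if (length(st)) tibble(experiment = design$experiment[i],
                             type = "stimulus", name = names(st),
                             level = unname(st)),
      if (length(inh)) tibble(experiment = design$experiment[i],
                              type = "inhibitor", name = names(inh),
                              level = unname(inh))
    )
  })
  # make every inhibitable name visible as an inhibitor with a 0 flag where
  # absent, so the MIDAS export carries a full column set
  pd <- perturbation_data(meas, treat, signals = observed)
  pd
}
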