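#' Normalized Hill transfer function
#'
#' \deqn{H(x) = \frac{x^n}{x^n + k^n}\,(1 + k^n)}
#' so that \eqn{H(0) = 0} and \eqn{H(1) = 1} for every admissible
#' \eqn{(n, k)}: regulator activities and drives live on the same
#' \eqn{[0, 1]} scale. `n` sets the steepness (switch-like for large `n`,
#' Michaelis-Menten-like for `n = 1`), `k` the half-saturation point.
#'
#' @param x Activity in \eqn{[0, 1]} (vectorized).
#' @param n Hill exponent, \eqn{\ge 1}.
#' @param k Half-saturation constant in \eqn{(0, 1]}.
#' @return Transfer values in \eqn{[0, 1]}.
#' @export
hill <- function(x, n, k) {
  if (any(k <= 0)) abort("k must be positive")
  if (any(x < -1e-12 | x > 1 + 1e-12)) abort("x must lie in [0, 1]")
  x <- pmin(pmax(x, 0), 1)
  kn <- k^n
  ifelse(x == 0, 0, x^n / (x^n + kn) * (1 + kn))
}

#' Hill transfer of an inhibited regulator
#'
#' The regulator's drive \eqn{x^n} is damped by \eqn{(1 - \mathrm{inh})} in
#' both numerator and denominator (the \eqn{1 + k^n} normalization is
#' untouched), so `inh = 0` reduces exactly to [hill()] and `inh = 1`
#' silences the regulator completely.
#'
#' @inheritParams hill
#' @param inh Inhibition strength in \eqn{[0, 1]}.
#' @export
hill_inhibited <- function(x, n, k, inh) {
  if (any(inh < 0 | inh > 1)) abort("inh must lie in [0, 1]")
  if (any(k <= 0)) abort("k must be positive")
  x <- pmin(pmax(x, 0), 1)
  kn <- k^n
  xn <- x^n * (1 - inh)
  ifelse(xn == 0, 0, xn / (xn + kn) * (1 + kn))
}

#' Continuous (multilinear) interpolation of a Boolean update rule
#'
#' Extends a truth table to continuous regulator activities: with `N`
#' regulators, the `2^N` structure weights `w` sit at the Boolean corners and
#' \deqn{\bar B = \sum_{x \in \{0,1\}^N} w_x \prod_k [x_k h_k + (1-x_k)(1-h_k)]}
#' Corner products form a partition of unity, so \eqn{\bar B} is a convex
#' combination of the weights and stays in \eqn{[\min w, \max w]}.
#'
#' Corner ordering: index `j = 0, ..., 2^N - 1` with regulator `k`'s Boolean
#' value equal to bit `k - 1` of `j` (so for two regulators the order is
#' `w00, w10, w01, w11`). An AND gate is `w = c(0, 0, 0, 1)`, OR is
#' `c(0, 1, 1, 0)` ... `c(0, 1, 1, 1)` for inclusive OR.
#'
#' @param h Numeric vector of `N` regulator activations in \eqn{[0, 1]}.
#' @param w Numeric vector of `2^N` structure weights in \eqn{[0, 1]}.
#' @return The interpolated drive, in \eqn{[\min w, \max w] \subseteq [0,1]}.
#' @export
boolean_homologue <- function(h, w) {
  N <- length(h)
  if (length(w) != 2^N) {
    abort(paste0("w must have length 2^N = ", 2^N, ", got ", length(w)))
  }
  if (N == 0) return(w[1])
  B <- 0
  for (j in seq_len(2^N) - 1L) {
    prod <- w[j + 1L]
    for (k in seq_len(N)) {
      prod <- prod * if (bitwAnd(bitwShiftR(j, k - 1L), 1L)) h[k] else (1 - h[k])
    }
    B <- B + prod
  }
  B
}

corner_labels <- function(N) {
  if (N == 0) return("w_")
  vapply(seq_len(2^N) - 1L, function(j) {
    paste0("w_", paste(vapply(seq_len(N), function(k)
      bitwAnd(bitwShiftR(j, k - 1L), 1L), integer(1)), collapse = ""))
  }, character(1))
}

#' Construct a logic-based ODE model on a network scaffold
#'
#' Each non-stimulus node `i` obeys
#' \deqn{\dot{\bar x}_i = (\bar B_i - \bar x_i) / \tau_i}
#' where \eqn{\bar B_i} interpolates a Boolean gate over the node's regulators
#' through normalized Hill transfers ([hill()], [boolean_homologue()]) and
#' \eqn{\tau_i} is the species' lifetime. Stimulus nodes are clamped to their
#' experimental level. Parentless nodes relax toward their single basal
#' weight.
#'
#' @param net A [network()] scaffold.
#' @param n,k Default Hill exponent / half-saturation for every edge.
#' @param tau Default lifetime (data time units) for every node.
#' @param gate Default gate for multi-input nodes: `"or"` (default) or
#'   `"and"`; single-input nodes start as plain activators.
#' @param observed Signals mapped by the observation function `g`; default all
#'   non-stimulus nodes.
#' @param inhibitor_mode `"node"` (the inhibitor damps the species' own
#'   derivative) or `"downstream"` (it damps the species' Hill terms in its
#'   targets).
#' @return An object of class `logic_ode_model`.
#' @export
logic_ode_model <- function(net, n = 2, k = 0.5, tau = 1,
                            gate = c("or", "and"), observed = NULL,
                            inhibitor_mode = c("node", "downstream")) {
  stopifnot(inherits(net, "ddn_network"))
  gate <- match.arg(gate)
  inhibitor_mode <- match.arg(inhibitor_mode)
  nodes <- attr(net, "nodes")
  stimuli <- attr(net, "stimuli")
  reg <- lapply(nodes, function(v) net$from[net$to == v])
  names(reg) <- nodes
  w <- lapply(nodes, function(v) {
    N <- length(reg[[v]])
    lbl <- corner_labels(N)
    if (N == 0) return(setNames(0, lbl))
    wv <- vapply(seq_len(2^N) - 1L, function(j) {
      on <- sum(vapply(seq_len(N), function(kk)
        bitwAnd(bitwShiftR(j, kk - 1L), 1L), integer(1)))
      if (gate == "and") as.numeric(on == N) else as.numeric(on > 0)
    }, numeric(1))
    setNames(wv, lbl)
  })
  names(w) <- nodes
  mk <- function(val) lapply(reg, function(r) setNames(rep(val, length(r)), r))
  m <- structure(
    list(
      nodes = nodes,
      stimuli = stimuli,
      regulators = reg,
      hill_n = mk(n),
      hill_k = mk(k),
      weights = w,
      tau = setNames(ifelse(nodes %in% stimuli, NA_real_, tau), nodes),
      observed = observed %||% setdiff(nodes, stimuli),
      inhibitor_mode = inhibitor_mode
    ),
    class = "logic_ode_model"
  )
  validate_model(m)
}

validate_model <- function(m) {
  for (v in m$nodes) {
    N <- length(m$regulators[[v]])
    if (length(m$weights[[v]]) != 2^N) {
      abort(paste0("node ", v, ": weights length must be 2^", N))
    }
    if (any(m$weights[[v]] < 0 | m$weights[[v]] > 1)) {
      abort(paste0("node ", v, ": weights must lie in [0, 1]"))
    }
    if (N > 0) {
      if (any(m$hill_n[[v]] < 1)) abort(paste0("node ", v, ": n must be >= 1"))
      if (any(m$hill_k[[v]] <= 0 | m$hill_k[[v]] > 1)) {
        abort(paste0("node ", v, ": k must lie in (0, 1]"))
      }
    }
    if (!v %in% m$stimuli && !(m$tau[[v]] > 0)) {
      abort(paste0("node ", v, ": tau must be positive"))
    }
  }
  m
}

#' @export
print.logic_ode_model <- function(x, ...) {
  cat("<logic_ode_model> ", length(x$nodes), " nodes (",
      length(x$stimuli), " stimuli), ",
      sum(lengths(x$regulators)), " active edges, inhibitor mode: ",
      x$inhibitor_mode, "\n", sep = "")
  for (v in setdiff(x$nodes, x$stimuli)) {
    r <- x$regulators[[v]]
    cat("  ", v, " <- ", if (length(r)) toString(r) else
      paste0("(basal ", signif(x$weights[[v]][1], 3), ")"), "\n", sep = "")
  }
  invisible(x)
}

#' Active edge list of a model
#' @param m A `logic_ode_model`.
#' @return Tibble with columns `from`, `to`.
#' @export
model_edges <- function(m) {
  purrr::map_dfr(m$nodes, function(v) {
    r <- m$regulators[[v]]
    if (length(r) == 0) tibble(from = character(), to = character())
    else tibble(from = r, to = v)
  })
}

#' Remove (deactivate) one edge of a model
#'
#' Setting a regulator's Hill term to zero is exactly equivalent to removing
#' the edge: corners where that regulator is "on" can never be reached, so the
#' weight array is collapsed to the regulator-off slice and the edge's Hill
#' parameters are dropped.
#'
#' @param m A `logic_ode_model`.
#' @param from,to Edge to remove.
#' @return The reduced model.
#' @export
deactivate_edge <- function(m, from, to) {
  r <- m$regulators[[to]]
  pos <- which(r == from)
  if (length(pos) != 1) abort(paste0("no active edge ", from, " -> ", to))
  N <- length(r)
  keep_j <- which(vapply(seq_len(2^N) - 1L, function(j)
    bitwAnd(bitwShiftR(j, pos - 1L), 1L) == 0L, logical(1)))
  wv <- unname(m$weights[[to]][keep_j])
  m$regulators[[to]] <- r[-pos]
  m$hill_n[[to]] <- m$hill_n[[to]][-pos]
  m$hill_k[[to]] <- m$hill_k[[to]][-pos]
  m$weights[[to]] <- setNames(wv, corner_labels(N - 1L))
  m
}

#' Time derivative of the logic-ODE state (reference implementation)
#'
#' Pure-R evaluation of the right-hand side, primarily for inspection and for
#' cross-checking the compiled integrator: stimulus nodes have derivative 0,
#' every other node moves toward its interpolated drive at rate
#' \eqn{1/\tau_i}, damped by \eqn{(1-\mathrm{inh}_i)} in `"node"` mode; in
#' `"downstream"` mode inhibited species enter their targets' gates through
#' [hill_inhibited()].
#'
#' @param m A `logic_ode_model`.
#' @param state Named (or model-ordered) state vector in \eqn{[0,1]^n}.
#' @param experiment List with `stimuli` (named levels) and `inhibitors`
#'   (named strengths in \eqn{[0,1]}), as from [get_experiment()] after
#'   applying an inhibition strength.
#' @param inhibitor_mode Override of the model's inhibitor mode.
#' @return Named derivative vector.
#' @export
node_derivative <- function(m, state, experiment = list(),
                            inhibitor_mode = NULL) {
  mode <- inhibitor_mode %||% m$inhibitor_mode
  if (!mode %in% c("node", "downstream")) {
    abort(paste0("unknown inhibitor_mode: ", mode))
  }
  x <- setNames(as.numeric(state), m$nodes)
  inh <- setNames(rep(0, length(m$nodes)), m$nodes)
  ex_inh <- experiment$inhibitors
  inh[names(ex_inh)[names(ex_inh) %in% m$nodes]] <-
    ex_inh[names(ex_inh) %in% m$nodes]
  dx <- setNames(rep(0, length(m$nodes)), m$nodes)
  for (v in setdiff(m$nodes, m$stimuli)) {
    r <- m$regulators[[v]]
    h <- if (length(r) == 0) numeric() else {
      vapply(seq_along(r), function(kk) {
        if (mode == "downstream" && inh[r[kk]] > 0) {
          hill_inhibited(x[r[kk]], m$hill_n[[v]][kk], m$hill_k[[v]][kk],
                         inh[r[kk]])
        } else {
          hill(x[r[kk]], m$hill_n[[v]][kk], m$hill_k[[v]][kk])
        }
      }, numeric(1))
    }
    B <- boolean_homologue(h, unname(m$weights[[v]]))
    d <- (B - x[v]) / m$tau[[v]]
    if (mode == "node") d <- d * (1 - inh[v])
    dx[v] <- d
  }
  dx
}

#' Initial state of an experiment
#'
#' Stimulus nodes start (and stay) at their experimental level; measured nodes
#' start at their t = 0 measurement when available; everything else starts at
#' 0.
#'
#' @noRd
initial_state <- function(m, experiment) {
  x0 <- setNames(rep(0, length(m$nodes)), m$nodes)
  st <- experiment$stimuli
  x0[names(st)[names(st) %in% m$nodes]] <- st[names(st) %in% m$nodes]
  v <- experiment$values
  if (!is.null(v) && !is.null(experiment$times) && length(experiment$times) > 0 &&
      experiment$times[1] <= 0) {
    y0 <- v[1, ]
    ok <- names(y0)[!is.na(y0) & names(y0) %in% m$nodes &
                      !names(y0) %in% names(st)]
    x0[ok] <- pmin(pmax(y0[ok], 0), 1)
  }
  x0
}

#' Simulate one experiment of a logic-ODE model
#'
#' Integrates the model with an adaptive Dormand-Prince RK45 scheme
#' (compiled), sampling the trajectory at the requested times. States are
#' clipped to \eqn{[0,1]} at output only.
#'
#' @param m A `logic_ode_model`.
#' @param experiment List with `stimuli` (named levels) and `inhibitors`
#'   (named 0/1 applied flags or strengths; flags are multiplied by
#'   `inh_strength`), optionally `times`/`values` for data-derived initial
#'   conditions.
#' @param times Sampling instants (sorted, \eqn{\ge 0}); defaults to
#'   `experiment$times`.
#' @param x0 Optional initial state override (named or model-ordered).
#' @param inh_strength Strength applied to binary inhibitor flags; default
#'   0.9.
#' @param rtol,atol Solver tolerances.
#' @param observed_only Return only observed signals.
#' @return A tibble `time`, `signal`, `value` in long (tidy) form.
#' @export
simulate_experiment <- function(m, experiment, times = NULL, x0 = NULL,
                                inh_strength = 0.9, rtol = 1e-6, atol = 1e-8,
                                observed_only = FALSE) {
  times <- times %||% experiment$times
  if (is.null(times)) abort("no sampling times given")
  if (is.unsorted(times)) abort("times must be sorted increasing")
  tr <- sim_matrix(m, experiment, times, x0 = x0, inh_strength = inh_strength,
                   rtol = rtol, atol = atol)
  keep <- if (observed_only) m$observed else m$nodes
  tibble(
    time = rep(times, times = length(keep)),
    signal = rep(keep, each = length(times)),
    value = as.vector(tr[, keep, drop = FALSE])
  )
}

# Matrix-valued simulation (time x node) used internally for speed.
sim_matrix <- function(m, experiment, times, x0 = NULL, inh_strength = 0.9,
                       rtol = 1e-6, atol = 1e-8) {
  cm <- compile_model(m)
  ex <- experiment_vectors(m, experiment, inh_strength)
  if (!is.null(x0)) {
    x0v <- if (!is.null(names(x0))) {
      out <- ex$x0; out[names(x0)] <- x0; out
    } else setNames(as.numeric(x0), m$nodes)
    ex$x0 <- x0v
  }
  tr <- tryCatch(
    sim_experiment_cpp(cm$cmodel, cm$par, ex$x0, ex$inh,
                       if (m$inhibitor_mode == "downstream") 1L else 0L,
                       as.numeric(times), 0, rtol, atol, 1000000L),
    error = function(e) abort(paste0("simulation failed",
      if (!is.null(experiment$id)) paste0(" (experiment ", experiment$id, ")"),
      ": ", conditionMessage(e)))
  )
  colnames(tr) <- m$nodes
  tr
}

# Clamp/expand an experiment description into model-ordered vectors.
experiment_vectors <- function(m, experiment, inh_strength = 0.9) {
  inh <- setNames(rep(0, length(m$nodes)), m$nodes)
  ei <- experiment$inhibitors
  if (length(ei) > 0) {
    ei <- ei[names(ei) %in% m$nodes]
    # binary applied flags become strengths; explicit strengths pass through
    v <- ifelse(ei %in% c(0, 1), ei * inh_strength, ei)
    inh[names(ei)] <- v
  }
  list(x0 = initial_state(m, experiment), inh = inh)
}

#' @export
tidy.logic_ode_model <- function(x, ...) {
  purrr::map_dfr(setdiff(x$nodes, x$stimuli), function(v) {
    r <- x$regulators[[v]]
    dplyr::bind_rows(
      if (length(r) > 0) tibble(node = v, parameter = "n", regulator = r,
                                value = unname(x$hill_n[[v]])),
      if (length(r) > 0) tibble(node = v, parameter = "k", regulator = r,
                                value = unname(x$hill_k[[v]])),
      tibble(node = v, parameter = names(x$weights[[v]]),
             regulator = NA_character_, value = unname(x$weights[[v]])),
      tibble(node = v, parameter = "tau", regulator = NA_character_,
             value = unname(x$tau[[v]]))
    )
  })
}

#' @export
glance.logic_ode_model <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes),
    n_stimuli = length(x$stimuli),
    n_edges = sum(lengths(x$regulators)),
    n_parameters = length(compile_model(x)$par),
    inhibitor_mode = x$inhibitor_mode
  )
}

#' Serialize / restore a model as JSON
#'
#' @param m A `logic_ode_model`.
#' @param path File path.
#' @return [write_model_json()] returns `path` invisibly; [read_model_json()]
#'   returns the model.
#' @export
write_model_json <- function(m, path) {
  doc <- list(
    nodes = m$nodes, stimuli = m$stimuli, observed = m$observed,
    inhibitor_mode = m$inhibitor_mode,
    tau = as.list(m$tau[setdiff(m$nodes, m$stimuli)]),
    nodes_spec = lapply(setdiff(m$nodes, m$stimuli), function(v) list(
      node = v, regulators = m$regulators[[v]],
      n = unname(m$hill_n[[v]]), k = unname(m$hill_k[[v]]),
      w = as.list(m$weights[[v]])
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  nodes <- doc$nodes; stimuli <- doc$stimuli %||% character()
  edges <- purrr::map_dfr(doc$nodes_spec, function(sp) {
    if (length(sp$regulators) == 0) tibble(from = character(), to = character())
    else tibble(from = unlist(sp$regulators), to = sp$node)
  })
  net <- network(edges, nodes = nodes, stimuli = stimuli)
  m <- logic_ode_model(net, observed = unlist(doc$observed),
                       inhibitor_mode = doc$inhibitor_mode)
  for (sp in doc$nodes_spec) {
    v <- sp$node
    r <- as.character(unlist(sp$regulators))
    m$regulators[[v]] <- r
    m$hill_n[[v]] <- setNames(as.numeric(unlist(sp$n)), r)
    m$hill_k[[v]] <- setNames(as.numeric(unlist(sp$k)), r)
    m$weights[[v]] <- unlist(sp$w)
    m$tau[[v]] <- as.numeric(doc$tau[[v]])
  }
  validate_model(m)
}
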