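test_that("the normalized Hill transfer fixes 0 and 1 and is monotone", {
  grid <- expand.grid(n = c(1, 2, 4, 8), k = c(0.1, 0.5, 0.9))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; k <- grid$k[i]
    expect_equal(hill(1, n, k), 1)
    expect_equal(hill(0, n, k), 0)
    x <- seq(0, 1, length.out = 101)
    expect_true(all(diff(hill(x, n, k)) >= -1e-12))
    expect_true(all(hill(x, n, k) >= 0 & hill(x, n, k) <= 1 + 1e-12))
  }
  expect_equal(hill(0.5, 2, 0.5), 0.625)
  expect_error(hill(0.5, 2, 0), "positive")
})

test_that("inhibited Hill interpolates between full transfer and silence", {
  x <- seq(0, 1, 0.1)
  for (n in c(1, 3)) for (k in c(0.3, 0.7)) {
    expect_equal(hill_inhibited(x, n, k, 0), hill(x, n, k))
    expect_equal(hill_inhibited(x, n, k, 1), rep(0, length(x)))
    # strictly decreasing in inh for interior x
    inh <- seq(0, 0.95, 0.05)
    vals <- vapply(inh, function(ii) hill_inhibited(0.6, n, k, ii), numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  expect_error(hill_inhibited(0.5, 2, 0.5, 1.2), "\\[0, 1\\]")
})

test_that("the Boolean interpolation hits its weights at saturated corners", {
  # AND gate behaviour (corner order w00, w10, w01, w11)
  expect_equal(boolean_homologue(c(1, 1), c(0, 0, 0, 1)), 1)
  expect_equal(boolean_homologue(c(1, 0), c(0, 0, 0, 1)), 0)
  expect_equal(boolean_homologue(c(0.3, 0.8), rep(0, 4)), 0)
  # corner enumeration for N = 1, 2, 3
  for (N in 1:3) {
    set.seed(N)
    w <- runif(2^N)
    for (j in seq_len(2^N) - 1) {
      h <- vapply(seq_len(N), function(k) bitwAnd(bitwShiftR(j, k - 1L), 1L),
                  integer(1))
      expect_equal(boolean_homologue(as.numeric(h), w), w[j + 1])
    }
  }
  expect_error(boolean_homologue(c(0.5, 0.5), c(0, 1)), "length")
})

test_that("corner products form a partition of unity", {
  for (N in 1:3) {
    set.seed(N + 10)
    for (r in 1:20) {
      h <- runif(N)
      # with all weights 1, the interpolation must equal exactly 1
      expect_equal(boolean_homologue(h, rep(1, 2^N)), 1, tolerance = 1e-12)
      # and it is a convex combination of the weights
      w <- runif(2^N)
      B <- boolean_homologue(h, w)
      expect_gte(B, min(w) - 1e-12)
      expect_lte(B, max(w) + 1e-12)
    }
  }
})

test_that("node derivatives vanish at fixed points and scale with tau", {
  m <- cascade_model()
  ex <- list(stimuli = c(L1 = 1), inhibitors = NULL)
  # fixed point: x_i = B_i for all dynamic nodes
  h1 <- hill(1, 2, 0.5); B1 <- h1  # X1 <- L1, activator (OR on one input)
  x1 <- B1
  B2 <- hill(x1, 2, 0.5)
  st <- c(L1 = 1, X1 = x1, X2 = B2)
  dx <- node_derivative(m, st, ex)
  expect_equal(unname(dx), rep(0, 3), tolerance = 1e-12)
  # doubling tau halves the derivative
  st2 <- c(L1 = 1, X1 = 0.2, X2 = 0.9)
  d1 <- node_derivative(m, st2, ex)
  m2 <- m; m2$tau[c("X1", "X2")] <- 2
  d2 <- node_derivative(m2, st2, ex)
  expect_equal(unname(d2[c("X1", "X2")]), unname(d1[c("X1", "X2")]) / 2)
  # stimulus derivative is always zero
  expect_equal(unname(d1["L1"]), 0)
})

test_that("node-mode inhibition with strength one freezes the node", {
  m <- cascade_model()
  ex <- list(stimuli = c(L1 = 1), inhibitors = c(X1 = 1))
  dx <- node_derivative(m, c(L1 = 1, X1 = 0.1, X2 = 0.4), ex)
  expect_equal(unname(dx["X1"]), 0)
  expect_error(node_derivative(m, c(1, 0, 0), ex, inhibitor_mode = "weird"),
               "inhibitor_mode")
})

test_that("single-node trajectories match the analytic exponential", {
  for (w0 in c(0.2, 0.8)) for (tau in c(0.5, 2)) for (x0 in c(0, 1)) {
    m <- basal_model(w0, tau = tau)
    times <- seq(0, 5, 0.5)
    tr <- simulate_experiment(m, list(stimuli = NULL, inhibitors = NULL),
                              times = times, x0 = c(X = x0))
    expected <- w0 + (x0 - w0) * exp(-times / tau)
    expect_equal(tr$value, expected, tolerance = 1e-5)
  }
})

test_that("a state at its fixed point stays constant", {
  m <- basal_model(0.6)
  tr <- simulate_experiment(m, list(), times = seq(0, 10, 1),
                            x0 = c(X = 0.6))
  expect_equal(tr$value, rep(0.6, 11), tolerance = 1e-7)
})

test_that("trajectories of random models stay inside the unit box", {
  for (s in 1:10) {
    cfg <- synthetic_config(n_nodes = 5, n_stimuli = 1, max_indegree = 2,
                            noise_sd = 0)
    tm <- generate_truth_model(cfg, seed = s)
    set.seed(s)
    x0 <- runif(5)
    x0[1] <- 1  # stimulus level
    ex <- list(stimuli = c(L1 = 1), inhibitors = NULL)
    tr <- elodin:::sim_matrix(tm$model, ex, seq(0, 20, 0.5), x0 = x0)
    expect_true(all(tr >= -1e-6 & tr <= 1 + 1e-6))
  }
})

test_that("downstream inhibition damps the inhibited species' outgoing edges", {
  m <- cascade_model()
  m$inhibitor_mode <- "downstream"
  ex_free <- list(stimuli = c(L1 = 1), inhibitors = NULL)
  ex_inh <- list(stimuli = c(L1 = 1), inhibitors = c(X1 = 0.9))
  st <- c(L1 = 1, X1 = 0.8, X2 = 0)
  d_free <- node_derivative(m, st, ex_free)
  d_inh <- node_derivative(m, st, ex_inh)
  # X1's own derivative is untouched, X2's drive is damped
  expect_equal(unname(d_inh["X1"]), unname(d_free["X1"]))
  expect_lt(unname(d_inh["X2"]), unname(d_free["X2"]))
  h_expect <- hill_inhibited(0.8, 2, 0.5, 0.9)
  expect_equal(unname(d_inh["X2"]), h_expect / 1)
})

test_that("deactivating an edge equals zeroing its Hill term", {
  # brute force: B with regulator k forced to H = 0 vs the collapsed gate
  set.seed(4)
  for (N in 2:3) {
    w <- runif(2^N)
    h <- runif(N)
    for (drop in seq_len(N)) {
      h0 <- h; h0[drop] <- 0
      full <- boolean_homologue(h0, w)
      keep_j <- which(vapply(seq_len(2^N) - 1L, function(j)
        bitwAnd(bitwShiftR(j, drop - 1L), 1L) == 0L, logical(1)))
      collapsed <- boolean_homologue(h[-drop], w[keep_j])
      expect_equal(full, collapsed, tolerance = 1e-12)
    }
  }
  # and on a whole model: derivatives agree pointwise
  m <- cascade_model()
  net3 <- network(data.frame(from = c("L1", "X1", "L1"),
                             to = c("X1", "X2", "X2")),
                  nodes = c("L1", "X1", "X2"), stimuli = "L1")
  m3 <- logic_ode_model(net3)
  m3red <- deactivate_edge(m3, "L1", "X2")
  ex <- list(stimuli = c(L1 = 1), inhibitors = NULL)
  st <- c(L1 = 1, X1 = 0.35, X2 = 0.7)
  # reduced model's X2 sees only X1; full model with the L1 edge silenced
  # (X2's stored regulator order is L1, X1)
  h_x1 <- hill(0.35, 2, 0.5)
  manual <- boolean_homologue(c(0, h_x1), unname(m3$weights[["X2"]]))
  expect_equal(unname(node_derivative(m3red, st, ex)["X2"]),
               manual - 0.7, tolerance = 1e-12)
})

test_that("model JSON documents round-trip", {
  cfg <- synthetic_config(noise_sd = 0)
  tm <- generate_truth_model(cfg, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(tm$model, path)
  back <- read_model_json(path)
  expect_equal(back$regulators, tm$model$regulators)
  expect_equal(back$weights, tm$model$weights)
  expect_equal(back$hill_n, tm$model$hill_n)
  expect_equal(back$tau, tm$model$tau)
  # identical simulations
  ex <- list(stimuli = c(L1 = 1, L2 = 0), inhibitors = NULL)
  t1 <- simulate_experiment(tm$model, ex, times = 0:5)
  t2 <- simulate_experiment(back, ex, times = 0:5)
  expect_equal(t1, t2)
})

test_that("compile/set_parameters is a faithful round-trip", {
  cfg <- synthetic_config(noise_sd = 0)
  tm <- generate_truth_model(cfg, seed = 8)
  cm <- compile_model(tm$model)
  m2 <- set_parameters(tm$model, cm$par)
  expect_equal(m2$hill_n, tm$model$hill_n)
  expect_equal(m2$weights, tm$model$weights)
  expect_equal(m2$tau, tm$model$tau)
})
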