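noise_free_benchmark <- function(seed, n_nodes = 4, n_stimuli = 1) {
  cfg <- synthetic_config(n_nodes = n_nodes, n_stimuli = n_stimuli,
                          max_indegree = 2, noise_sd = 0)
  tm <- generate_truth_model(cfg, seed = seed)
  design <- generate_design(tm$model$observed, ligands = tm$model$stimuli,
                            inhibitable = tm$model$observed)
  pd <- simulate_dataset(tm$model, design, cfg)
  list(cfg = cfg, tm = tm, pd = pd)
}

test_that("the objective vanishes for the generating model and is additive", {
  b <- noise_free_benchmark(21)
  expect_equal(objective(b$tm$model, b$pd), 0)
  # additivity over experiments
  ids <- experiment_ids(b$pd)
  half1 <- b$pd; keep1 <- half1$measurements$experiment %in% ids[1:3]
  half1$measurements <- half1$measurements[keep1, ]
  half1$treatments <- half1$treatments[half1$treatments$experiment %in% ids[1:3], ]
  half2 <- b$pd; keep2 <- !b$pd$measurements$experiment %in% ids[1:3]
  half2$measurements <- half2$measurements[keep2, ]
  half2$treatments <- half2$treatments[!half2$treatments$experiment %in% ids[1:3], ]
  m2 <- b$tm$model
  m2$tau[["X1"]] <- m2$tau[["X1"]] * 2  # perturb so F > 0
  expect_equal(objective(m2, b$pd),
               objective(m2, half1) + objective(m2, half2), tolerance = 1e-10)
})

test_that("a single perturbed data point contributes its squared residual", {
  b <- noise_free_benchmark(22)
  pd2 <- b$pd
  i <- which(!is.na(pd2$measurements$value))[5]
  pd2$measurements$value[i] <- pd2$measurements$value[i] + 0.1
  expect_equal(objective(b$tm$model, pd2), 0.01, tolerance = 1e-9)
})

test_that("AIC matches the closed form and its monotonicities", {
  expect_equal(aic(2, 8, 2), 4 + 16 * log(0.25))
  expect_equal(aic(2, 8, 2) - aic(2, 8, 1), 2)
  expect_lt(aic(1, 10, 3), aic(2, 10, 3))
  expect_true(is.finite(aic(0, 10, 3)))
  expect_error(aic(1, 0, 1), "positive")
})

test_that("active parameter count follows the node-structure formula", {
  m <- cascade_model()  # X1: 1 regulator, X2: 1 regulator
  expect_equal(count_active_parameters(m), 2 * (2 + 2 + 1))
  net3 <- network(data.frame(from = c("L1", "X1", "L1"),
                             to = c("X1", "X2", "X2")),
                  nodes = c("L1", "X1", "X2"), stimuli = "L1")
  m3 <- logic_ode_model(net3)
  # X1: 2+2+1, X2 (two regulators): 4+4+1
  expect_equal(count_active_parameters(m3), 5 + 9)
  m3r <- deactivate_edge(m3, "L1", "X2")
  expect_lt(count_active_parameters(m3r), count_active_parameters(m3))
  # parentless node counts only its basal weight
  m3rr <- deactivate_edge(m3r, "X1", "X2")
  expect_equal(count_active_parameters(m3rr), 5 + 1)
})

test_that("training respects bounds, budget and seeding", {
  b <- noise_free_benchmark(23)
  m0 <- logic_ode_model(b$tm$network, observed = b$tm$model$observed)
  fit1 <- train_model(m0, b$pd, budget = 150, polish = 0, prefit = FALSE,
                      seed = 7)
  fit2 <- train_model(m0, b$pd, budget = 150, polish = 0, prefit = FALSE,
                      seed = 7)
  expect_identical(fit1$par, fit2$par)
  expect_identical(fit1$objective, fit2$objective)
  cm <- compile_model(m0)
  expect_true(all(fit1$par >= cm$lower - 1e-12 & fit1$par <= cm$upper + 1e-12))
  expect_true(is.finite(fit1$objective))
  # monotone best-F trace
  expect_true(all(diff(fit1$trace$best_F) <= 0))
  expect_error(train_model(m0, b$pd, budget = 150,
                           bounds = parameter_bounds(k = c(0.5, 0.2))),
               "lower < upper")
})

test_that("training recovers a small noise-free cascade", {
  b <- noise_free_benchmark(24, n_nodes = 3, n_stimuli = 1)
  m0 <- logic_ode_model(b$tm$network, observed = b$tm$model$observed)
  fit <- train_model(m0, b$pd, budget = 3000, seed = 1)
  expect_lt(fit$objective, 1e-3)
  # gate behaviour matches the truth at saturated corners
  for (v in setdiff(b$tm$model$nodes, b$tm$model$stimuli)) {
    w_true <- round(b$tm$model$weights[[v]])
    w_fit <- round(fit$model$weights[[v]])
    expect_equal(unname(w_fit), unname(w_true), label = paste("gate of", v))
  }
})

test_that("an empty dataset is rejected before optimization", {
  m <- cascade_model()
  pd <- perturbation_data(
    tibble::tibble(experiment = character(), time = numeric(),
                   signal = character(), value = numeric()),
    tibble::tibble(), signals = c("X1", "X2"))
  expect_error(train_model(m, pd, budget = 100), "empty")
})

test_that("reduction leaves an edgeless model unchanged", {
  net <- network(data.frame(from = character(), to = character()),
                 nodes = c("A", "B"), stimuli = character())
  m <- logic_ode_model(net, observed = c("A", "B"))
  meas <- tidyr::expand_grid(experiment = "e1", time = c(0, 1, 2),
                             signal = c("A", "B"))
  meas$value <- 0.5
  pd <- perturbation_data(meas, tibble::tibble(), signals = c("A", "B"))
  fit <- train_model(m, pd, budget = 100, polish = 0, prefit = FALSE, seed = 1)
  red <- reduce_model(fit$model, fit, pd, local_budget = 50, seed = 1)
  expect_equal(nrow(red$removed), 0)
  expect_equal(model_edges(red$model), model_edges(fit$model))
})

test_that("reduction removes a planted inert edge and lowers AIC stepwise", {
  b <- noise_free_benchmark(42, n_nodes = 4, n_stimuli = 1)
  tm <- b$tm
  nodes <- attr(tm$network, "nodes")
  true_e <- paste(tm$network$from, tm$network$to)
  extra <- setdiff(
    paste(nodes[1], setdiff(nodes, c(nodes[1], attr(tm$network, "stimuli")))),
    true_e)[1]
  pf <- strsplit(extra, " ")[[1]]
  net2 <- network(rbind(as.data.frame(tm$network)[c("from", "to")],
                        data.frame(from = pf[1], to = pf[2])),
                  nodes = nodes, stimuli = attr(tm$network, "stimuli"))
  m0 <- logic_ode_model(net2, observed = tm$model$observed)
  fit <- train_model(m0, b$pd, budget = 4000, seed = 2)
  red <- reduce_model(fit$model, fit, b$pd, local_budget = 2500, seed = 2)
  e <- paste(model_edges(red$model)$from, model_edges(red$model)$to)
  expect_false(extra %in% e)
  expect_true(all(diff(red$result$aic_trace) < 0))
  expect_lte(red$result$aic, fit$aic + 1e-6)
  # final edge set is a subset of the initial one
  expect_true(all(e %in% paste(net2$from, net2$to)))
})

test_that("identical seeds give identical reduced models", {
  b <- noise_free_benchmark(26, n_nodes = 3, n_stimuli = 1)
  m0 <- logic_ode_model(b$tm$network, observed = b$tm$model$observed)
  run <- function() {
    fit <- train_model(m0, b$pd, budget = 400, polish = 10, seed = 5)
    reduce_model(fit$model, fit, b$pd, local_budget = 200, seed = 5)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$result$par, r2$result$par)
  expect_identical(model_edges(r1$model), model_edges(r2$model))
})
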