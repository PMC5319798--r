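pred_from_obs <- function(pd, delta = 0) {
  p <- pd$measurements
  names(p)[names(p) == "value"] <- "obs"
  p$value <- p$obs + delta
  p[c("experiment", "time", "signal", "value")]
}

test_that("RMSE reproduces hand computations", {
  pd <- random_dataset(seed = 41)
  expect_equal(rmse(pred_from_obs(pd), pd), 0)
  expect_equal(rmse(pred_from_obs(pd, 0.1), pd), 0.1, tolerance = 1e-12)
  # 4-point toy with residuals 0, .1, .2, .3
  obs <- tibble::tibble(experiment = "e", time = c(0, 1, 0, 1),
                        signal = rep(c("A", "B"), each = 2),
                        value = c(0.5, 0.5, 0.5, 0.5))
  pd2 <- perturbation_data(obs, tibble::tibble())
  pred <- obs
  pred$value <- pred$value + c(0, 0.1, 0.2, 0.3)
  expect_equal(rmse(pred, pd2), sqrt(0.14 / 4))
  # missing observations are skipped (row 2 after ordering carries the
  # 0.2 residual)
  pd3 <- pd2; pd3$measurements$value[2] <- NA
  expect_equal(rmse(pred, pd3), sqrt(0.10 / 3))
  # no overlap is an error
  pred_far <- pred; pred_far$time <- pred_far$time + 100
  expect_error(rmse(pred_far, pd2), "overlap")
})

test_that("precision-recall matches the worked toy example", {
  truth <- network(data.frame(from = c("A", "C"), to = c("B", "D")),
                   nodes = c("A", "B", "C", "D"))
  scores <- tibble::tibble(
    from = c("A", "B", "C", "D"), to = c("B", "A", "D", "C"),
    confidence = c(0.9, 0.8, 0.7, 0.1))
  pr <- pr_analysis(scores, truth)
  expect_equal(pr$aupr, 0.5 * 1.0 + 0.5 * (2 / 3), tolerance = 1e-12)
  # perfect ranking
  pr2 <- pr_analysis(scores[c(1, 3), ], truth)
  expect_equal(pr2$aupr, 1)
  # degenerate single candidate
  truth1 <- network(data.frame(from = "A", to = "B"), nodes = c("A", "B"))
  pr3 <- pr_analysis(tibble::tibble(from = "A", to = "B", confidence = 0.4),
                     truth1)
  top <- pr3$curve[1, ]
  expect_equal(top$precision, 1)
  expect_equal(top$recall, 1)
  expect_error(pr_analysis(scores,
                           network(data.frame(from = character(),
                                              to = character()),
                                   nodes = c("A", "B"))),
               "positive")
})

test_that("ROC spans perfect, reversed and random rankings", {
  truth <- network(data.frame(from = c("A", "C"), to = c("B", "D")),
                   nodes = c("A", "B", "C", "D"))
  perfect <- tibble::tibble(from = c("A", "C"), to = c("B", "D"),
                            confidence = c(1, 0.9))
  expect_equal(roc_analysis(perfect, truth)$auroc, 1)
  # reversed: all negatives scored above all positives
  nodes <- c("A", "B", "C", "D")
  all_pairs <- expand.grid(from = nodes, to = nodes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  tr_key <- c("A B", "C D")
  all_pairs$confidence <- ifelse(paste(all_pairs$from, all_pairs$to) %in%
                                   tr_key, 0.01, 0.99)
  expect_equal(roc_analysis(all_pairs, truth)$auroc, 0)
  # random scores on a balanced toy are null-distributed around 1/2
  set.seed(7)
  n_edge <- 20
  labels <- rep(c(TRUE, FALSE), each = n_edge / 2)
  aurocs <- vapply(1:2000, function(i) {
    bf_pr_roc(runif(n_edge), labels)$auroc
  }, numeric(1))
  se <- sd(aurocs) / sqrt(length(aurocs))
  expect_lt(abs(mean(aurocs) - 0.5), 3 * se + 1e-3)
  all_true <- network(data.frame(from = c("A", "B"), to = c("B", "A")),
                      nodes = c("A", "B"))
  expect_error(roc_analysis(tibble::tibble(from = "A", to = "B",
                                           confidence = 1), all_true),
               "negative")
})

test_that("curve areas equal the brute-force oracle on random instances", {
  nodes <- paste0("n", 1:5)
  for (s in 1:8) {
    set.seed(s + 50)
    all_pairs <- expand.grid(from = nodes, to = nodes,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
    truth_idx <- sample(nrow(all_pairs), 6)
    truth <- network(all_pairs[truth_idx, ], nodes = nodes)
    scores <- all_pairs
    scores$confidence <- round(runif(nrow(scores)), 2)  # force some ties
    pr <- pr_analysis(scores, truth, nodes = nodes)
    roc <- roc_analysis(scores, truth, nodes = nodes)
    key <- paste(all_pairs$from, all_pairs$to)
    labels <- key %in% paste(truth$from, truth$to)
    bf <- bf_pr_roc(scores$confidence, labels)
    expect_equal(pr$aupr, bf$aupr, tolerance = 1e-12)
    expect_equal(roc$auroc, bf$auroc, tolerance = 1e-12)
  }
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  nodes <- paste0("n", 1:5)
  set.seed(99)
  all_pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  truth <- network(all_pairs[sample(nrow(all_pairs), 7), ], nodes = nodes)
  scores <- all_pairs
  scores$confidence <- runif(nrow(scores))
  roc <- roc_analysis(scores, truth, nodes = nodes)
  labels <- paste(all_pairs$from, all_pairs$to) %in%
    paste(truth$from, truth$to)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores$confidence,
                                              direction = "<")))
  expect_equal(roc$auroc, as.numeric(ref), tolerance = 1e-10)
})

test_that("areas are invariant under monotone score transforms", {
  nodes <- paste0("n", 1:4)
  set.seed(61)
  all_pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  truth <- network(all_pairs[sample(nrow(all_pairs), 4), ], nodes = nodes)
  scores <- all_pairs
  scores$confidence <- runif(nrow(scores))
  s2 <- scores; s2$confidence <- exp(5 * s2$confidence)
  expect_equal(pr_analysis(scores, truth)$aupr, pr_analysis(s2, truth)$aupr)
  expect_equal(roc_analysis(scores, truth)$auroc,
               roc_analysis(s2, truth)$auroc)
})

test_that("confusion counts partition positives and negatives everywhere", {
  nodes <- paste0("n", 1:4)
  set.seed(62)
  all_pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  truth <- network(all_pairs[sample(nrow(all_pairs), 5), ], nodes = nodes)
  scores <- all_pairs
  scores$confidence <- sample(c(0, 0.3, 0.7, 1), nrow(scores), replace = TRUE)
  cv <- pr_analysis(scores, truth)$curve
  expect_true(all(cv$tp + cv$fn == 5))
  expect_true(all(cv$fp + cv$tn == nrow(all_pairs) - 5))
  expect_true(all(cv$tp + cv$fp + cv$fn + cv$tn == nrow(all_pairs)))
})

test_that("a wrong-direction prediction is a false positive", {
  truth <- network(data.frame(from = "A", to = "B"), nodes = c("A", "B", "C"))
  wrong <- tibble::tibble(from = "B", to = "A", confidence = 1)
  cv <- pr_analysis(wrong, truth)$curve
  expect_equal(cv$fp[1], 1)
  expect_equal(cv$tp[1], 0)
  # but symmetrization credits it
  pr_sym <- pr_analysis(wrong, truth, symmetrize = TRUE)
  expect_equal(pr_sym$curve$tp[1], 1)
})
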