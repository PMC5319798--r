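# Small fixtures built in code, shared across test files.

# A MIDAS file with one stimulus, two times, one signal (2 experiments).
write_tiny_midas <- function(path) {
  writeLines(c(
    "TR:EGF,DA:ALL,DV:Akt",
    "0,0,0.10",
    "0,10,0.20",
    "1,0,0.10",
    "1,10,0.80"
  ), path)
  path
}

# A complete-grid random dataset with stimuli and inhibitor flags.
random_dataset <- function(seed = 1, n_signals = 3, n_exp = 4,
                           times = c(0, 5, 10)) {
  set.seed(seed)
  signals <- paste0("S", seq_len(n_signals))
  exps <- paste0("e", seq_len(n_exp))
  meas <- expand.grid(experiment = exps, time = times, signal = signals,
                      stringsAsFactors = FALSE)
  meas$value <- round(runif(nrow(meas)), 4)
  # distinct stimulus levels keep treatment signatures unique per experiment
  treat <- do.call(rbind, lapply(seq_along(exps), function(i) {
    rbind(
      data.frame(experiment = exps[i], type = "stimulus", name = "EGF",
                 level = i / 10),
      data.frame(experiment = exps[i], type = "inhibitor", name = "S1",
                 level = as.numeric(i %% 2 == 0))
    )
  }))
  perturbation_data(meas, treat, signals = signals)
}

# A two-node cascade model (L1 -> X1 -> X2) with fixed parameters.
cascade_model <- function(n = 2, k = 0.5, tau = 1) {
  net <- network(data.frame(from = c("L1", "X1"), to = c("X1", "X2")),
                 nodes = c("L1", "X1", "X2"), stimuli = "L1")
  logic_ode_model(net, n = n, k = k, tau = tau)
}

# A single dynamic node relaxing to a constant drive w0 (no parents).
basal_model <- function(w0, tau = 1, node = "X") {
  net <- network(data.frame(from = character(), to = character()),
                 nodes = node, stimuli = character())
  m <- logic_ode_model(net, tau = tau, observed = node)
  m$weights[[node]][] <- w0
  m
}

# Independent brute-force AUPR/AUROC oracle: enumerate all distinct
# thresholds and accumulate the areas directly from the definition.
bf_pr_roc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels); N <- sum(!labels)
  prev_r <- 0; aupr <- 0
  fpr <- numeric(); rec <- numeric()
  for (th in ths) {
    sel <- scores >= th
    tp <- sum(labels & sel); fp <- sum(!labels & sel)
    p <- if (tp + fp > 0) tp / (tp + fp) else 1
    r <- tp / P
    aupr <- aupr + p * (r - prev_r)
    prev_r <- r
    fpr <- c(fpr, fp / N); rec <- c(rec, r)
  }
  xs <- c(0, fpr, 1); ys <- c(0, rec, 1)
  auroc <- sum(diff(xs) * (utils::head(ys, -1) + ys[-1]) / 2)
  list(aupr = aupr, auroc = auroc)
}
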