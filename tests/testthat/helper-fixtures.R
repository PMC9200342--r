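# Small synthetic fixtures shared across the test files. Everything is
# generated in code; sizes are kept far below the default cohort scale so the suite
# stays fast.

tiny_config <- function(seed = 1L, samples_per_week = 48, noise = TRUE) {
  circ <- default_circadian()
  if (!noise) circ$noise_sd <- 0
  cohort_config(
    group_sizes = c(naive = 2, injured = 2, sham = 2),
    weeks = list(naive = 1L, injured = 1:2, sham = 1:2),
    samples_per_week = samples_per_week,
    circadian = circ,
    seed = seed
  )
}

tiny_bins <- function(seed = 1L, n_bins = 6) {
  bin_observations(simulate_cohort(tiny_config(seed)), n_bins)
}

# Random record-style feature set with prescribed class counts.
random_features <- function(counts, seed = 1L, sd = 1) {
  withr::with_seed(seed, {
    labels <- rep(0:2, times = counts)
    n <- sum(counts)
    tibble::tibble(
      animal_id = sprintf("a%03d", seq_len(n)),
      group = c("naive", "injured", "sham")[labels + 1],
      week = 1L,
      bin = 0L,
      label = labels,
      distance_mm = rnorm(n, 10 * labels, sd),
      temperature_c = rnorm(n, 36 + labels, sd / 10),
      separation_mm = rnorm(n, 100 + 5 * labels, sd),
      transitions = rnorm(n, 20 + 2 * labels, sd)
    )
  })
}

# Majority-class stub model factory for LOOCV plumbing tests: ignores the
# features entirely.
majority_stub <- function(x_train, y_train, weights) {
  maj <- as.integer(names(which.max(table(y_train))))
  function(x_new) rep(maj, nrow(x_new))
}

# 1-nearest-neighbour stub (memorising predictor).
nn1_stub <- function(x_train, y_train, weights) {
  function(x_new) {
    apply(x_new, 1, function(r) {
      d <- colSums((t(x_train) - r)^2)
      y_train[which.min(d)]
    })
  }
}

expect_tree_depths_le <- function(rf_fit, max_depth) {
  depths <- vapply(seq_len(rf_fit$num.trees), function(k) {
    info <- ranger::treeInfo(rf_fit, k)
    depth <- integer(nrow(info))
    for (r in seq_len(nrow(info))) {
      kids <- c(info$leftChild[r], info$rightChild[r])
      kids <- kids[!is.na(kids)]
      if (length(kids)) depth[kids + 1L] <- depth[r] + 1L
    }
    max(depth)
  }, integer(1))
  expect_true(all(depths <= max_depth))
}

# Independent nested-loop counting oracle for the classification metrics.
brute_force_metrics <- function(truth, pred, k = 3) {
  cm <- matrix(0L, k, k)
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  prec <- rec <- f1 <- numeric(k)
  for (c in seq_len(k)) {
    tp <- cm[c, c]; fp <- sum(cm[, c]) - tp; fn <- sum(cm[c, ]) - tp
    prec[c] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[c] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[c] <- if (prec[c] + rec[c] == 0) 0 else
      2 * prec[c] * rec[c] / (prec[c] + rec[c])
  }
  list(acc = sum(diag(cm)) / length(truth), cm = cm, prec = prec,
       rec = rec, f1 = f1)
}
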