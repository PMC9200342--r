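test_that("record standardizer matches brute-force moments", {
  feats <- random_features(c(30, 40, 30), seed = 1)
  std <- fit_standardizer(feats)
  for (ch in hca_channels()) {
    expect_equal(std$mean[[ch]], sum(feats[[ch]]) / nrow(feats),
                 tolerance = 1e-12)
    expect_equal(std$sd[[ch]],
                 sqrt(sum((feats[[ch]] - mean(feats[[ch]]))^2) /
                        (nrow(feats) - 1)), tolerance = 1e-12)
  }
  z <- apply_standardizer(std, feats)
  expect_equal(unname(colMeans(as.matrix(z[, hca_channels()]))), rep(0, 4),
               tolerance = 1e-9)
  expect_equal(unname(apply(as.matrix(z[, hca_channels()]), 2, sd)),
               rep(1, 4), tolerance = 1e-9)
})

test_that("standardizer handles two-point, mean and zero-variance cases", {
  two <- random_features(c(1, 1, 0))
  two[, hca_channels()] <- 0
  two[2, hca_channels()] <- 2
  std <- fit_standardizer(two)
  expect_equal(unname(std$mean), rep(1, 4))
  expect_equal(unname(std$sd), rep(sqrt(2), 4))
  # a held-out point equal to the training mean maps to zero
  held <- two[1, ]
  held[, hca_channels()] <- 1
  expect_equal(unname(unlist(
    apply_standardizer(std, held)[, hca_channels()]
  )), rep(0, 4))
  # zero-variance feature: sd guarded to 1 with a warning
  const <- random_features(c(3, 3, 0))
  const$distance_mm <- 5
  expect_warning(stdc <- fit_standardizer(const), "distance_mm")
  expect_equal(stdc$sd[["distance_mm"]], 1)
})

test_that("standardizer is fitted on training rows only (leakage sentinel)", {
  feats <- random_features(c(20, 20, 20), seed = 2)
  train <- feats[1:40, ]
  std1 <- fit_standardizer(train)
  poisoned <- feats
  poisoned[41:60, hca_channels()] <- 1e6
  std2 <- fit_standardizer(poisoned[1:40, ])
  expect_identical(std1, std2)
})

test_that("sequence standardizer pools unpadded positions and re-zeroes pads", {
  bins <- bin_observations(simulate_cohort(cohort_config(
    group_sizes = c(naive = 1, injured = 1),
    weeks = list(naive = 1L, injured = 1L),
    samples_per_week = 45 * 6, seed = 9
  )), 6)
  seqs <- sequence_features(bins, 48)
  expect_true(any(!seqs$mask))
  std <- fit_standardizer(seqs)
  # oracle: moments over real positions only
  for (c in 1:4) {
    vals <- seqs$data[, , c][seqs$mask]
    expect_equal(std$mean[[c]], mean(vals), tolerance = 1e-12)
    expect_equal(std$sd[[c]], sd(vals), tolerance = 1e-12)
  }
  z <- apply_standardizer(std, seqs)
  for (c in 1:4) {
    expect_equal(mean(z$data[, , c][z$mask]), 0, tolerance = 1e-9)
    expect_equal(sd(z$data[, , c][z$mask]), 1, tolerance = 1e-9)
    expect_true(all(z$data[, , c][!z$mask] == 0))
  }
})

test_that("class weights follow the balanced convention", {
  expect_equal(unname(class_weights(rep(0:2, times = c(10, 10, 10)))),
               rep(1, 3))
  w <- class_weights(rep(0:2, times = c(96, 324, 288)))
  expect_equal(unname(w), c(2.4583, 0.7284, 0.8194), tolerance = 1e-4)
  # weighted counts recover the dataset size
  expect_equal(sum(w * c(96, 324, 288)), 708)
  # scale invariance
  w2 <- class_weights(rep(0:2, times = 2 * c(96, 324, 288)))
  expect_equal(w, w2)
  expect_error(class_weights(rep(1, 5)), "2 distinct")
})

test_that("SMOTE balances counts, keeps originals, interpolates parents", {
  feats <- random_features(c(5, 20, 20), seed = 3)
  aug <- smote_oversample(feats, k = 5, seed = 7)
  expect_equal(unname(table(aug$label)), rep(20L, 3), ignore_attr = TRUE)
  expect_equal(as.data.frame(aug[seq_len(nrow(feats)), ]),
               as.data.frame(feats), ignore_attr = TRUE)
  par <- attr(aug, "smote_parents")
  expect_equal(nrow(par), 15)
  x <- as.matrix(aug[, hca_channels()])
  for (r in seq_len(nrow(par))) {
    p <- x[aug$animal_id == "smote", , drop = FALSE][r, ]
    a <- x[par$parent_i[r], ]; b <- x[par$parent_j[r], ]
    # distance from the synthetic point to the segment [a, b]
    ab <- b - a
    t <- if (sum(ab^2) == 0) 0 else
      min(max(sum((p - a) * ab) / sum(ab^2), 0), 1)
    expect_lt(sqrt(sum((p - (a + t * ab))^2)), 1e-9)
    # parents share the synthetic point's class
    expect_equal(feats$label[par$parent_i[r]], aug$label[nrow(feats) + r])
    expect_equal(feats$label[par$parent_j[r]], aug$label[nrow(feats) + r])
  }
  # convexity: synthetic points stay within their class's bounding box
  for (ch in hca_channels()) {
    rng <- range(feats[[ch]][feats$label == 0])
    synth <- aug[[ch]][aug$animal_id == "smote" & aug$label == 0]
    expect_true(all(synth >= rng[1] - 1e-12 & synth <= rng[2] + 1e-12))
  }
})

test_that("SMOTE contracts: balanced input unchanged, tiny class errors", {
  feats <- random_features(c(10, 10, 10), seed = 4)
  expect_identical(smote_oversample(feats, seed = 1), feats)
  solo <- random_features(c(1, 10, 10), seed = 5)
  expect_error(smote_oversample(solo, seed = 1), "fewer than 2")
  # determinism
  unb <- random_features(c(4, 12, 9), seed = 6)
  expect_identical(smote_oversample(unb, seed = 3), smote_oversample(unb, seed = 3))
})

test_that("stratified split respects ratios per class", {
  feats <- random_features(c(40, 100, 60), seed = 8)
  sp <- stratified_split(feats, c(0.7, 0.15, 0.15), seed = 2)
  tab <- table(sp$label, sp$.split)
  expect_equal(unname(tab[, "train"]), c(28, 70, 42))
  expect_true(all(abs(tab[, "validation"] - c(6, 15, 9)) <= 1))
  expect_equal(rowSums(tab), c(`0` = 40, `1` = 100, `2` = 60))
  expect_error(stratified_split(feats, c(0.5, 0.5)), "ratios")
})
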