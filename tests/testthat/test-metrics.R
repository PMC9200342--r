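test_that("perfect predictions score perfectly", {
  m <- compute_metrics(tibble::tibble(truth = c(0, 1, 2, 1, 0),
                                      pred = c(0, 1, 2, 1, 0)))
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_precision, 1)
  expect_equal(m$macro_recall, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(sum(m$confusion) - sum(diag(m$confusion)), 0)
})

test_that("hand-enumerated example reproduces per-class arithmetic", {
  m <- compute_metrics(tibble::tibble(truth = c(0, 1, 2, 1),
                                      pred = c(0, 1, 1, 1)))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$per_class$precision, c(1, 2 / 3, 0))  # class 2 never predicted
  expect_equal(m$macro_precision, 5 / 9)
  expect_equal(m$per_class$recall, c(1, 1, 0))
  expect_equal(m$n, 4L)
})

test_that("metrics match the brute-force counting oracle on random data", {
  withr::with_seed(99, {
    truth <- sample(0:2, 1000, replace = TRUE, prob = c(0.2, 0.5, 0.3))
    pred <- sample(0:2, 1000, replace = TRUE)
  })
  m <- compute_metrics(tibble::tibble(truth = truth, pred = pred))
  o <- brute_force_metrics(truth, pred)
  expect_equal(m$accuracy, o$acc, tolerance = 1e-12)
  expect_equal(unname(m$confusion), o$cm, ignore_attr = TRUE)
  expect_equal(m$per_class$precision, o$prec, tolerance = 1e-12)
  expect_equal(m$per_class$recall, o$rec, tolerance = 1e-12)
  expect_equal(m$per_class$f1, o$f1, tolerance = 1e-12)
  expect_equal(m$macro_precision, mean(o$prec), tolerance = 1e-12)
  expect_equal(m$macro_recall, mean(o$rec), tolerance = 1e-12)
  # macro-F1 is the mean of per-class F1, not the harmonic mean of P and R
  expect_equal(m$macro_f1, mean(o$f1), tolerance = 1e-12)
  support <- rowSums(o$cm)
  expect_equal(m$weighted_f1, sum(o$f1 * support) / sum(support),
               tolerance = 1e-12)
  # tidiers
  expect_equal(nrow(generics::tidy(m)), 3)
  expect_equal(generics::glance(m)$accuracy, o$acc)
})

test_that("metrics validate labels and reject empty input", {
  expect_error(compute_metrics(tibble::tibble(truth = integer(),
                                              pred = integer())), "No predictions")
  expect_error(compute_metrics(tibble::tibble(truth = 4, pred = 0)), "0..2")
})

test_that("class balance reproduces printed share arithmetic", {
  cb <- class_balance(rep(0:2, times = c(96, 324, 288)))
  expect_equal(cb$n, c(96L, 324L, 288L))
  expect_equal(cb$share_pct[cb$class == 1], 46)
  expect_equal(cb$share_pct[cb$class == 2], 41)
})

test_that("PCA embedding is centred, ordered and sign-fixed", {
  feats <- random_features(c(30, 40, 30), seed = 21)
  emb <- pca_embedding(feats, 2)
  ev <- attr(emb, "explained_variance")
  expect_gte(ev[1], ev[2])
  expect_equal(mean(emb$.pc1), 0, tolerance = 1e-9)
  expect_equal(mean(emb$.pc2), 0, tolerance = 1e-9)
  rot <- attr(emb, "loadings")
  for (j in 1:2) expect_gt(rot[which.max(abs(rot[, j])), j], 0)
  # the mean point projects to the origin
  mf <- feats[1, ]
  mf[hca_channels()] <- as.list(colMeans(feats[, hca_channels()]))
  pm <- predict(prcomp(as.matrix(feats[, hca_channels()]), center = TRUE),
                as.matrix(mf[, hca_channels()]))
  expect_equal(unname(pm[1, 1:2]), c(0, 0), tolerance = 1e-9)
})

test_that("full-rank PCA reconstructs 2-D data exactly", {
  feats <- random_features(c(20, 20, 0), seed = 22)
  feats$separation_mm <- 0    # keep exactly two informative dimensions
  feats$transitions <- 0
  expect_warning(std <- fit_standardizer(feats), "Zero-variance")
  x <- as.matrix(feats[, c("distance_mm", "temperature_c")])
  p <- prcomp(x, center = TRUE)
  recon <- p$x[, 1:2] %*% t(p$rotation[, 1:2])
  recon <- sweep(recon, 2, -p$center, `-`)
  expect_equal(recon, x, tolerance = 1e-9, ignore_attr = TRUE)
  # package embedding agrees up to the fixed sign convention
  emb <- pca_embedding(feats, 2)
  expect_equal(abs(emb$.pc1), abs(unname(p$x[, 1])), tolerance = 1e-9)
  const <- feats
  const[, hca_channels()] <- 1
  expect_error(pca_embedding(const), "degenerate")
})

test_that("evaluation report is deterministic and complete", {
  withr::with_seed(30, {
    t1 <- sample(0:2, 60, TRUE); p1 <- sample(0:2, 60, TRUE)
  })
  m1 <- compute_metrics(tibble::tibble(truth = t1, pred = p1))
  m2 <- compute_metrics(tibble::tibble(truth = t1, pred = t1))
  rep1 <- evaluation_report(list(rf = m1, deep = m2))
  expect_equal(nrow(rep1), 2)
  expect_equal(rep1$model, c("rf", "deep"))
  expect_equal(rep1$accuracy_pct[2], 100)
  expect_identical(format(rep1),
                   format(evaluation_report(list(rf = m1, deep = m2))))
  # confusion-matrix row sums equal per-class support
  expect_equal(unname(rowSums(m1$confusion)),
               as.integer(table(factor(t1, 0:2))))
  # plots build without error
  expect_s3_class(autoplot(m1), "ggplot")
  expect_s3_class(autoplot(pca_embedding(random_features(c(10, 10, 10)))),
                  "ggplot")
})
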