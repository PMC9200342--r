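test_that("conv block applies conv -> BN -> ReLU -> pool with the stated shapes", {
  withr::with_seed(1, x <- matrix(rnorm(48 * 4), 48, 4))
  f <- conv_block_1d(x, filters = 32, kernel_size = 3, seed = 2)
  expect_equal(dim(f), c(24L, 32L))               # pool halves the length
  h <- attr(f, "activation")
  expect_equal(dim(h), c(48L, 32L))
  expect_true(all(h >= 0))                        # ReLU range
  expect_equal(f, apply(array(h, c(2, 24, 32)), c(2, 3), max),
               ignore_attr = TRUE)                # pooling is a windowed max
  # zero input with zero-initialised bias gives a zero pre-activation
  y0 <- attr(conv_block_1d(matrix(0, 48, 4), 8, seed = 3), "preactivation")
  expect_true(all(y0 == 0))
  expect_error(conv_block_1d(matrix(0, 2, 4), 8, kernel_size = 3), "shorter")
})

test_that("deep model parameter count matches a hand computation", {
  m <- build_deep_model(spec = deep_model_spec(seed = 1))
  # independent arithmetic from the layer geometry (bias-free convs under BN)
  conv1 <- 3 * 4 * 32 + 3 * 32 * 64
  bns <- 2 * 32 + 2 * 64 + 2 * 16 + 2 * 32
  lstm <- 64 * (4 * 64) + 64 * (4 * 64) + 4 * 64
  conv2 <- 3 * 3 * 4 * 16 + 3 * 3 * 16 * 32
  flat <- (8 %/% 4) * (48 %/% 4) * 32
  dense <- (64 + flat) * 64 + 64
  out <- 64 * 3 + 3
  expect_equal(n_parameters(m), conv1 + bns + lstm + conv2 + dense + out)
})

test_that("seeded model building is reproducible", {
  w <- function(m) lapply(m$layers, function(ly) {
    stats::setNames(lapply(ly$par, function(p) ly[[p]]), ly$par)
  })
  m1 <- build_deep_model(spec = deep_model_spec(seed = 4))
  m2 <- build_deep_model(spec = deep_model_spec(seed = 4))
  expect_identical(w(m1), w(m2))
  m3 <- build_deep_model(spec = deep_model_spec(seed = 5))
  expect_false(identical(w(m1), w(m3)))
  f1 <- build_ffnn(4, ffnn_spec(seed = 4))
  f2 <- build_ffnn(4, ffnn_spec(seed = 4))
  expect_identical(w(f1), w(f2))
})

test_that("softmax outputs are row-stochastic and argmax-consistent", {
  withr::with_seed(6, {
    n <- 10
    xs <- array(rnorm(n * 48 * 4), c(n, 48, 4))
    xi <- array(rnorm(n * 8 * 48 * 4), c(n, 8, 48, 4))
    xf <- matrix(rnorm(n * 4), n, 4)
  })
  deep <- build_deep_model(spec = deep_model_spec(seed = 7))
  p <- predict_proba(deep, list(seq = xs, scaleo = xi))
  expect_equal(dim(p), c(10L, 3L))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_equal(predict(deep, list(seq = xs, scaleo = xi)),
               max.col(p, ties.method = "first") - 1L)
  ff <- build_ffnn(4, ffnn_spec(seed = 8))
  pf <- predict_proba(ff, xf)
  expect_equal(rowSums(pf), rep(1, 10), tolerance = 1e-6)
})

test_that("the FFNN is dense -> BN -> dense -> BN -> softmax", {
  ff <- build_ffnn(4, ffnn_spec(seed = 1))
  expect_equal(layer_sequence(ff),
               c("dense", "bn", "dense", "bn", "dense_softmax"))
})

test_that("training separates well-separated classes perfectly", {
  withr::with_seed(10, {
    x <- rbind(matrix(rnorm(45 * 4, 0), 45), matrix(rnorm(45 * 4, 10), 45),
               matrix(rnorm(45 * 4, -10), 45))
  })
  y <- rep(0:2, each = 45)
  m <- train_nn(build_ffnn(4, ffnn_spec(seed = 2)), scale(x), y, epochs = 30)
  expect_equal(mean(predict(m, scale(x)) == y), 1.0)
  # loss decreases over training
  expect_lt(m$history$loss[nrow(m$history)], m$history$loss[1])
})

test_that("class weighting behaves like the loss multiplier it is", {
  withr::with_seed(11, x <- matrix(rnorm(60 * 4), 60, 4))
  y <- rep(0:2, each = 20)
  unw <- train_nn(build_ffnn(4, ffnn_spec(seed = 3)), x, y, epochs = 3)
  ones <- train_nn(build_ffnn(4, ffnn_spec(seed = 3)), x, y,
                   weights = c(`0` = 1, `1` = 1, `2` = 1), epochs = 3)
  expect_equal(unw$history, ones$history)       # all-equal weights: identity
  dbl <- train_nn(build_ffnn(4, ffnn_spec(seed = 3)), x, y,
                  weights = c(`0` = 2, `1` = 1, `2` = 1), epochs = 3)
  expect_gt(dbl$history$loss[1], ones$history$loss[1])
})

test_that("random-forest baseline respects the depth cap", {
  feats <- random_features(c(20, 30, 25), seed = 12)
  fit <- fit_baseline(make_baseline("random_forest"),
                      feats[, hca_channels()], feats$label, seed = 1)
  expect_tree_depths_le(fit$fit, 4)
  pr <- predict(fit, feats[, hca_channels()])
  expect_true(all(pr %in% 0:2))
  prob <- predict(fit, feats[, hca_channels()], type = "prob")
  expect_equal(rowSums(prob), rep(1, nrow(feats)), tolerance = 1e-9)
})

test_that("SVM baseline is one-vs-one with unit cost", {
  feats <- random_features(c(20, 30, 25), seed = 13)
  fit <- fit_baseline(make_baseline("svm"), feats[, hca_channels()],
                      feats$label, weights = class_weights(feats$label))
  expect_equal(fit$fit$cost, 1)
  expect_equal(fit$fit$nclasses, 3L)
  expect_length(fit$fit$rho, 3L)      # K(K-1)/2 pairwise classifiers
  expect_true(all(predict(fit, feats[, hca_channels()]) %in% 0:2))
  expect_error(make_baseline("boost"), "arg")
})

test_that("invalid training inputs are rejected with diagnostics", {
  expect_error(train_nn(build_ffnn(4, ffnn_spec(seed = 1)),
                        matrix(0, 4, 4), c(0, 1, 2, 5)), "Labels")
  expect_error(predict_proba(build_ffnn(4, ffnn_spec(seed = 1)),
                             matrix(0, 2, 7)), "width")
  m <- build_deep_model(spec = deep_model_spec(seed = 1))
  expect_error(
    predict_proba(m, list(seq = array(0, c(2, 20, 4)),
                          scaleo = array(0, c(2, 8, 48, 4)))), "shapes")
})
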