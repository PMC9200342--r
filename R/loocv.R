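#' Leave-one-out cross-validation
#'
#' Headline evaluation scheme: each binned observation takes a turn as a
#' singleton test set while the model is retrained on all the others. All
#' preprocessing that can leak information is redone inside every fold:
#' the standardiser is fitted on the training part only, class weights are
#' recomputed from the training labels only, and (for the deep model)
#' scaleograms are recomputed from the per-fold standardised sequences. The
#' held-out observation therefore never influences its own fold's
#' preprocessing or training.
#'
#' @param bins Binned observations from [bin_observations()].
#' @param model `"svm"`, `"rf"`, `"ffnn"`, `"deep"`, or a custom factory
#'   `function(x_train, y_train, weights)` returning a function
#'   `function(x_new) -> integer class` (useful for stubs and oracles).
#' @param max_folds If non-`NULL`, evaluate only a label-stratified, seeded
#'   subsample of this many folds instead of all N (each selected fold still
#'   trains on all N - 1 remaining observations). Intended for expensive
#'   models; the full LOOCV is the default.
#' @param seed Integer seed driving fold subsampling and per-fold model seeds.
#' @param epochs Optional override of the neural models' training epochs.
#' @param scales,wavelet Scaleogram settings for the deep model.
#' @param spec Optional model spec ([deep_model_spec()], [ffnn_spec()] or
#'   [make_baseline()]) overriding the defaults for the chosen model.
#' @param use_smote If `TRUE` (shallow record-style models only), SMOTE
#'   augmentation is applied to each fold's *training* data after
#'   standardisation; held-out observations are never touched. Disabled by
#'   default, mirroring the headline comparison.
#' @param keep_fold_details Also return each fold's fitted standardiser and
#'   class weights (attribute `fold_details`), for leakage auditing.
#' @param verbose Print fold progress.
#' @return A tibble of class `hc_loocv`: one row per evaluated fold with
#'   `obs` (row index into `bins`), provenance columns, `truth`, `pred`,
#'   probability columns `p0, p1, p2` (`NA` for models without probability
#'   output) and `valid`.
#' @export
loocv <- function(bins, model = "rf", max_folds = NULL, seed = 1L,
                  epochs = NULL, scales = 1:8, wavelet = "morlet",
                  spec = NULL, use_smote = FALSE, keep_fold_details = FALSE,
                  verbose = FALSE) {
  n <- nrow(bins)
  if (n < 2) abort("LOOCV needs at least 2 observations.")
  labels <- as.integer(bins$label)
  is_name <- is.character(model)
  if (is_name) model <- match.arg(model, c("svm", "rf", "ffnn", "deep"))
  if (!is_name && !is.function(model)) {
    abort("`model` must be a model name or a factory function.")
  }
  use_sequences <- is_name && identical(model, "deep")
  if (use_smote && (!is_name || model %in% "deep")) {
    abort("SMOTE is only supported for the record-style shallow models.")
  }

  if (use_sequences) {
    seqs <- sequence_features(bins)
  } else {
    feats <- record_features(bins)
  }

  folds <- seq_len(n)
  if (!is.null(max_folds) && max_folds < n) {
    folds <- sort(stratified_fold_sample(labels, max_folds, seed))
  }

  details <- if (keep_fold_details) vector("list", n) else NULL
  rows <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    i <- folds[fi]
    train_idx <- setdiff(seq_len(n), i)
    fold_seed <- seed + i
    res <- tryCatch(
      run_fold(i, train_idx, labels, model, is_name,
               if (use_sequences) seqs else feats, use_sequences,
               fold_seed, epochs, scales, wavelet, spec, use_smote),
      hc_fold_error = function(e) e
    )
    if (inherits(res, "condition")) {
      warn(paste0("Fold ", i, " invalid: ", conditionMessage(res)))
      rows[[fi]] <- tibble::tibble(
        obs = i, truth = labels[i], pred = NA_integer_,
        p0 = NA_real_, p1 = NA_real_, p2 = NA_real_, valid = FALSE
      )
    } else {
      rows[[fi]] <- tibble::tibble(
        obs = i, truth = labels[i], pred = res$pred,
        p0 = res$probs[1], p1 = res$probs[2], p2 = res$probs[3], valid = TRUE
      )
      if (keep_fold_details) details[[i]] <- res$details
    }
    if (verbose && fi %% 10 == 0) {
      message("fold ", fi, "/", length(folds))
    }
  }
  out <- purrr::list_rbind(rows)
  out <- dplyr::bind_cols(
    bins[out$obs, c("animal_id", "group", "week", "bin")], out
  )
  class(out) <- c("hc_loocv", class(out))
  attr(out, "model") <- if (is_name) model else "custom"
  if (keep_fold_details) attr(out, "fold_details") <- details
  out
}

stratified_fold_sample <- function(labels, max_folds, seed) {
  n <- length(labels)
  withr::with_seed(seed, {
    by_class <- split(seq_len(n), labels)
    take <- round(max_folds * vapply(by_class, length, integer(1)) / n)
    # fix rounding drift while keeping proportions
    while (sum(take) > max_folds) take[which.max(take)] <- take[which.max(take)] - 1L
    while (sum(take) < max_folds) take[which.min(take)] <- take[which.min(take)] + 1L
    unlist(purrr::map2(by_class, take, function(idx, k) {
      sample(idx, min(k, length(idx)))
    }), use.names = FALSE)
  })
}

fold_abort <- function(msg) {
  rlang::abort(msg, class = "hc_fold_error")
}

run_fold <- function(i, train_idx, labels, model, is_name, data,
                     use_sequences, fold_seed, epochs, scales, wavelet,
                     spec, use_smote) {
  y_train <- labels[train_idx]
  if (!setequal(unique(y_train), unique(labels))) {
    fold_abort("training fold lost a class entirely")
  }
  weights <- class_weights(y_train)
  if (use_sequences) {
    train <- subset_sequences(data, train_idx)
    test <- subset_sequences(data, i)
    std <- fit_standardizer(train)
    train <- apply_standardizer(std, train)
    test <- apply_standardizer(std, test)
    sc_train <- batch_scaleograms(train, scales, wavelet)
    sc_test <- batch_scaleograms(test, scales, wavelet)
    mspec <- spec %||% deep_model_spec()
    mspec$seed <- fold_seed
    net <- build_deep_model(
      seq_shape = dim(train$data)[2:3],
      scaleo_shape = dim(sc_train$data)[2:4], spec = mspec
    )
    net <- train_nn(net, list(seq = train$data, scaleo = sc_train$data),
                    y_train, weights = weights, epochs = epochs)
    probs <- predict_proba(net, list(seq = test$data, scaleo = sc_test$data))
    pred <- max.col(probs, ties.method = "first") - 1L
    return(list(pred = pred, probs = as.numeric(probs),
                details = list(standardizer = std, class_weights = weights)))
  }

  train <- data[train_idx, ]
  test <- data[i, ]
  std <- fit_standardizer(train)
  train <- apply_standardizer(std, train)
  test <- apply_standardizer(std, test)
  x_test <- as.matrix(test[, hca_channels()])
  details <- list(standardizer = std, class_weights = weights)

  if (!is_name) {
    predictor <- model(as.matrix(train[, hca_channels()]), y_train, weights)
    pred <- as.integer(predictor(x_test))
    return(list(pred = pred, probs = rep(NA_real_, 3), details = details))
  }
  if (use_smote) {
    train <- smote_oversample(train, seed = fold_seed)
    y_train <- as.integer(train$label)
    weights <- class_weights(labels[train_idx])  # weights from original fold
  }
  x_train <- as.matrix(train[, hca_channels()])
  if (model == "ffnn") {
    mspec <- spec %||% ffnn_spec()
    mspec$seed <- fold_seed
    net <- train_nn(build_ffnn(4, mspec), x_train, y_train,
                    weights = weights, epochs = epochs)
    probs <- predict_proba(net, x_test)
    pred <- max.col(probs, ties.method = "first") - 1L
    return(list(pred = pred, probs = as.numeric(probs), details = details))
  }
  bspec <- spec %||% make_baseline(if (model == "svm") "svm" else "random_forest")
  fit <- fit_baseline(bspec, x_train, y_train, weights = weights,
                      seed = fold_seed)
  pred <- predict(fit, x_test)
  probs <- if (bspec$name == "svm") rep(NA_real_, 3) else
    as.numeric(predict(fit, x_test, type = "prob"))
  list(pred = pred, probs = probs, details = details)
}
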