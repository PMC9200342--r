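#' Fit a standardiser on training data only
#'
#' Estimates per-feature location and scale (z-score parameters) from a
#' training subset. For record-style features each of the four channel-mean
#' columns gets its own (mean, sd); for sequence sets one (mean, sd) per
#' channel is pooled over all *unpadded* time positions, so the padding zeros
#' never contaminate the moments. Zero-variance features have their sd
#' replaced by 1 with a warning, so applying the transform is always defined.
#'
#' Standardisation parameters must only ever be fitted on the training part
#' of a split or fold; [loocv()] does this per fold automatically.
#'
#' @param x A [record_features()] tibble or an [sequence_features()] object.
#' @param ... Unused.
#' @return An object of class `hc_standardizer`.
#' @export
fit_standardizer <- function(x, ...) UseMethod("fit_standardizer")

#' @export
fit_standardizer.data.frame <- function(x, ...) {
  feats <- as.matrix(x[, hca_channels()])
  if (nrow(feats) == 0) abort("Cannot fit a standardizer on 0 rows.")
  mu <- colMeans(feats)
  sigma <- apply(feats, 2, sd)
  if (nrow(feats) == 1) sigma[] <- 0
  sigma <- guard_sd(sigma)
  structure(list(mode = "record", mean = mu, sd = sigma),
            class = "hc_standardizer")
}

#' @export
fit_standardizer.hc_sequences <- function(x, ...) {
  ch <- hca_channels()
  mu <- numeric(4); sigma <- numeric(4)
  for (c in 1:4) {
    vals <- x$data[, , c][x$mask]
    if (length(vals) == 0) abort("Cannot fit a standardizer on 0 samples.")
    mu[c] <- mean(vals)
    sigma[c] <- if (length(vals) > 1) sd(vals) else 0
  }
  names(mu) <- ch; names(sigma) <- ch
  structure(list(mode = "sequence", mean = mu, sd = guard_sd(sigma)),
            class = "hc_standardizer")
}

guard_sd <- function(sigma) {
  zero <- !is.finite(sigma) | sigma == 0
  if (any(zero)) {
    warn(paste0("Zero-variance feature(s) ",
                paste(names(sigma)[zero], collapse = ", "),
                "; sd replaced by 1."))
    sigma[zero] <- 1
  }
  sigma
}

#' Apply a fitted standardiser
#'
#' Transforms features to z-scores using parameters estimated by
#' [fit_standardizer()]. For sequence sets the transform is mask-preserving:
#' padded positions are reset to exactly zero after scaling.
#'
#' @param params An `hc_standardizer`.
#' @param x Data of the same kind the standardiser was fitted on.
#' @return Standardised data of the same class as `x`.
#' @export
apply_standardizer <- function(params, x) {
  stopifnot(inherits(params, "hc_standardizer"))
  ch <- hca_channels()
  if (params$mode == "record") {
    stopifnot(is.data.frame(x))
    for (c in ch) x[[c]] <- (x[[c]] - params$mean[[c]]) / params$sd[[c]]
    x
  } else {
    stopifnot(inherits(x, "hc_sequences"))
    for (c in seq_along(ch)) {
      x$data[, , c] <- (x$data[, , c] - params$mean[[c]]) / params$sd[[c]]
    }
    for (c in 1:4) x$data[, , c][!x$mask] <- 0
    x
  }
}

#' Balanced class weights
#'
#' Computes the balanced-weight convention `w_c = N / (K * n_c)` where `N` is
#' the number of labelled observations, `K` the number of distinct classes
#' present and `n_c` the count of class `c`. Minority classes therefore
#' receive the largest weight, and the weighted counts satisfy
#' `sum(n_c * w_c) = N`. Used as per-class loss multipliers instead of
#' resampling.
#'
#' @param labels Integer class vector.
#' @return Named numeric vector of weights (names are the class labels).
#' @export
#' @examples
#' class_weights(rep(c(0, 1, 2), times = c(96, 324, 288)))
class_weights <- function(labels) {
  counts <- table(labels)
  if (length(counts) < 2) {
    abort("Class weights need >= 2 distinct classes.")
  }
  n <- length(labels); k <- length(counts)
  w <- n / (k * as.numeric(counts))
  names(w) <- names(counts)
  w
}

#' SMOTE oversampling of minority classes
#'
#' Synthetic minority over-sampling: each synthetic point is a random convex
#' combination `x_i + u * (x_j - x_i)`, `u ~ U(0, 1)`, of a minority-class
#' point `x_i` and one of its `k` nearest same-class neighbours `x_j`
#' (Euclidean distance on the four feature columns). After augmentation every
#' class count equals the majority count; original rows are preserved
#' verbatim and come first. Intended for *training* data only — never apply
#' it to evaluation folds, and it is deliberately not defined for sequence
#' sets.
#'
#' @param features A [record_features()] tibble.
#' @param k Number of nearest neighbours considered (default 5; capped at
#'   `n_c - 1` for a class of size `n_c`).
#' @param seed Integer seed.
#' @return The augmented tibble. Synthetic rows have `animal_id = "smote"`
#'   and carry an attribute `smote_parents`: a tibble with `row` (index into
#'   the result), `parent_i`, `parent_j` (indices into the input) and `u`.
#' @export
smote_oversample <- function(features, k = 5, seed = 1L) {
  if (k < 1) abort("`k` must be >= 1.")
  counts <- table(features$label)
  n_max <- max(counts)
  feats <- as.matrix(features[, hca_channels()])
  parents <- list()
  synth <- list()
  withr::with_seed(seed, {
    for (cls in names(counts)) {
      need <- n_max - counts[[cls]]
      if (need == 0) next
      idx <- which(features$label == as.integer(cls))
      if (length(idx) < 2) {
        abort(paste0("Class ", cls, " has fewer than 2 samples; SMOTE needs >= 2."))
      }
      kk <- min(k, length(idx) - 1)
      d <- as.matrix(stats::dist(feats[idx, , drop = FALSE]))
      diag(d) <- Inf
      nn <- t(apply(d, 1, function(r) order(r)[seq_len(kk)]))
      base <- idx[sample.int(length(idx), need, replace = TRUE)]
      pick <- sample.int(kk, need, replace = TRUE)
      nbr <- idx[nn[cbind(match(base, idx), pick)]]
      u <- runif(need)
      new_feats <- feats[base, , drop = FALSE] +
        u * (feats[nbr, , drop = FALSE] - feats[base, , drop = FALSE])
      row <- features[rep(1, need), ]
      row$animal_id <- "smote"
      row$group <- features$group[base]
      row$week <- features$week[base]
      row$bin <- NA_integer_
      row$label <- as.integer(cls)
      for (j in seq_along(hca_channels())) {
        row[[hca_channels()[j]]] <- new_feats[, j]
      }
      synth[[cls]] <- row
      parents[[cls]] <- tibble::tibble(parent_i = base, parent_j = nbr, u = u)
    }
  })
  if (length(synth) == 0) return(features)
  out <- dplyr::bind_rows(features, purrr::list_rbind(unname(synth)))
  par <- purrr::list_rbind(unname(parents))
  par$row <- nrow(features) + seq_len(nrow(par))
  attr(out, "smote_parents") <- par[, c("row", "parent_i", "parent_j", "u")]
  out
}

#' Stratified train/validation/test split
#'
#' Seeded, label-stratified partition of a record-style feature set into
#' training, validation and test subsets (default ratios 0.7 / 0.15 / 0.15).
#' Provided for provisional hold-out evaluation; headline evaluation uses
#' [loocv()].
#'
#' @param features A [record_features()] tibble.
#' @param ratios Length-3 numeric vector summing to 1.
#' @param seed Integer seed.
#' @return The input tibble with an added `.split` factor column
#'   (`train`/`validation`/`test`).
#' @export
stratified_split <- function(features, ratios = c(0.7, 0.15, 0.15), seed = 1L) {
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-8) {
    abort("`ratios` must be three numbers summing to 1.")
  }
  split <- character(nrow(features))
  withr::with_seed(seed, {
    for (cls in unique(features$label)) {
      idx <- which(features$label == cls)
      idx <- sample(idx)
      n <- length(idx)
      n_train <- round(ratios[1] * n)
      n_val <- round(ratios[2] * n)
      split[idx[seq_len(n_train)]] <- "train"
      split[idx[n_train + seq_len(min(n_val, n - n_train))]] <- "validation"
      split[idx[setdiff(seq_len(n), seq_len(n_train + n_val))]] <- "test"
    }
  })
  features$.split <- factor(split, levels = c("train", "validation", "test"))
  features
}
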