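#' Classification metrics from fold predictions
#'
#' Builds the K x K confusion matrix (rows = truth, columns = prediction) and
#' computes accuracy plus per-class precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)` and `F1 = 2PR / (P + R)`. Undefined 0/0 ratios (e.g. a
#' never-predicted class) are defined as 0. Macro values are the unweighted
#' means of the per-class values — macro-F1 is the mean of per-class F1
#' scores, not the harmonic mean of macro precision and recall; weighted
#' (support-weighted) variants are reported alongside.
#'
#' @param predictions An [loocv()] result, or any data frame with integer
#'   `truth` and `pred` columns.
#' @param n_classes Number of classes (default 3).
#' @return An object of class `hc_metrics`.
#' @export
compute_metrics <- function(predictions, n_classes = 3) {
  if (nrow(predictions) == 0) abort("No predictions supplied.")
  ok <- !is.na(predictions$pred)
  truth <- as.integer(predictions$truth[ok])
  pred <- as.integer(predictions$pred[ok])
  if (length(truth) == 0) abort("All folds are invalid; nothing to score.")
  if (any(c(truth, pred) < 0 | c(truth, pred) >= n_classes)) {
    abort(paste0("Labels must lie in 0..", n_classes - 1, "."))
  }
  lev <- 0:(n_classes - 1)
  cm <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(truth = lev, pred = lev))
  tp <- unname(diag(cm))
  fp <- unname(colSums(cm)) - tp
  fn <- unname(rowSums(cm)) - tp
  precision <- safe_ratio(tp, tp + fp)
  recall <- safe_ratio(tp, tp + fn)
  f1 <- safe_ratio(2 * precision * recall, precision + recall)
  support <- rowSums(cm)
  per_class <- tibble::tibble(
    class = lev, support = as.integer(support),
    precision = precision, recall = recall, f1 = f1
  )
  wsum <- function(v) sum(v * support) / sum(support)
  structure(
    list(
      n = length(truth),
      n_invalid = sum(!ok),
      accuracy = sum(tp) / length(truth),
      macro_precision = mean(precision),
      macro_recall = mean(recall),
      macro_f1 = mean(f1),
      weighted_precision = wsum(precision),
      weighted_recall = wsum(recall),
      weighted_f1 = wsum(f1),
      per_class = per_class,
      confusion = cm
    ),
    class = "hc_metrics"
  )
}

safe_ratio <- function(num, den) ifelse(den == 0, 0, num / den)

#' @export
print.hc_metrics <- function(x, ...) {
  cat(sprintf(
    "<hc_metrics> n = %d | accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
    x$n, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1
  ))
  print(x$confusion)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.hc_metrics <- function(x, ...) x$per_class

#' @export
glance.hc_metrics <- function(x, ...) {
  tibble::tibble(
    n = x$n, accuracy = x$accuracy,
    macro_precision = x$macro_precision, macro_recall = x$macro_recall,
    macro_f1 = x$macro_f1,
    weighted_precision = x$weighted_precision,
    weighted_recall = x$weighted_recall, weighted_f1 = x$weighted_f1
  )
}

#' Class balance of a labelled dataset
#'
#' Counts observations per class and their nearest-integer percentage shares
#' of the dataset.
#'
#' @param labels Integer class vector.
#' @return A tibble with `class`, `n` and `share_pct` columns.
#' @export
#' @examples
#' class_balance(rep(c(0, 1, 2), times = c(96, 324, 288)))
class_balance <- function(labels) {
  counts <- table(labels)
  tibble::tibble(
    class = as.integer(names(counts)),
    n = as.integer(counts),
    share_pct = round(100 * as.integer(counts) / length(labels))
  )
}

#' Two-component PCA embedding of the record features
#'
#' Mean-centred projection of the per-bin channel means onto the leading
#' principal axes, as used to visualise class overlap. The sign of each
#' component is fixed so that its largest-magnitude loading is positive.
#'
#' @param features A [record_features()] tibble.
#' @param n_components Number of components (default 2).
#' @return An object of class `hc_pca`: a tibble of scores (`.pc1`, `.pc2`,
#'   ... plus provenance columns) with attributes `explained_variance`
#'   (fractions) and `loadings`.
#' @export
pca_embedding <- function(features, n_components = 2) {
  x <- as.matrix(features[, hca_channels()])
  if (nrow(x) <= n_components) abort("Need more observations than components.")
  if (all(apply(x, 2, sd) == 0)) {
    abort("Features are constant; PCA is degenerate.")
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(p$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- paste0(".pc", seq_len(k))
  out <- dplyr::bind_cols(
    features[, intersect(c("animal_id", "group", "week", "bin", "label"),
                         names(features))],
    tibble::as_tibble(scores)
  )
  ev <- p$sdev^2 / sum(p$sdev^2)
  attr(out, "explained_variance") <- ev[seq_len(k)]
  attr(out, "loadings") <- rot
  class(out) <- c("hc_pca", class(out))
  out
}

#' @export
glance.hc_pca <- function(x, ...) {
  ev <- attr(x, "explained_variance")
  tibble::tibble(component = seq_along(ev), explained_variance = ev)
}
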