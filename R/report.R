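#' Comparison table across evaluated models
#'
#' Collates the headline metrics of several models into one deterministic
#' table (accuracy as a percentage, macro precision / recall / F1), in the
#' order the models are supplied.
#'
#' @param metrics Named list of [compute_metrics()] results; names are the
#'   model labels.
#' @return A tibble of class `hc_report`, one row per model.
#' @export
evaluation_report <- function(metrics) {
  stopifnot(is.list(metrics), length(metrics) > 0,
            !is.null(names(metrics)), all(nzchar(names(metrics))))
  out <- purrr::list_rbind(purrr::imap(metrics, function(m, nm) {
    stopifnot(inherits(m, "hc_metrics"))
    tibble::tibble(
      model = nm, n = m$n,
      accuracy_pct = 100 * m$accuracy,
      macro_precision = m$macro_precision,
      macro_recall = m$macro_recall,
      macro_f1 = m$macro_f1,
      weighted_f1 = m$weighted_f1
    )
  }))
  class(out) <- c("hc_report", class(out))
  attr(out, "metrics") <- metrics
  out
}

#' @export
format.hc_report <- function(x, ...) {
  header <- sprintf("%-24s %6s %10s %10s %8s %8s", "Model", "n",
                    "Acc (%)", "Precision", "Recall", "F1")
  body <- sprintf("%-24s %6d %10.2f %10.3f %8.3f %8.3f",
                  x$model, x$n, x$accuracy_pct, x$macro_precision,
                  x$macro_recall, x$macro_f1)
  paste(c(header, body), collapse = "\n")
}

#' @export
print.hc_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Confusion-matrix heatmap
#'
#' @param object An [compute_metrics()] result.
#' @param ... Unused.
#' @return A ggplot object: counts per (truth, prediction) cell.
#' @export
autoplot.hc_metrics <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object$confusion))
  names(df) <- c("truth", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$truth))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted class", y = "True class", fill = "Count") +
    ggplot2::theme_minimal()
}

#' PCA scatter of the binned dataset
#'
#' @param object An [pca_embedding()] result.
#' @param ... Unused.
#' @return A ggplot object of the first two components coloured by group.
#' @export
autoplot.hc_pca <- function(object, ...) {
  ev <- attr(object, "explained_variance")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$.pc1, y = .data$.pc2,
                                       colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
      colour = "Group"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Weekly activity traces of a cohort
#'
#' Group-averaged channel traces over the session, faceted by week — the
#' standard visual check that injured animals show a flattened circadian
#' rhythm in week 1 with progressive recovery.
#'
#' @param cohort Cohort tibble.
#' @param channel Channel to plot (default `"distance_mm"`).
#' @return A ggplot object.
#' @export
plot_cohort <- function(cohort, channel = "distance_mm") {
  stopifnot(channel %in% hca_channels())
  avg <- dplyr::summarise(
    dplyr::group_by(cohort, .data$group, .data$week, .data$timestamp),
    value = mean(.data[[channel]]), .groups = "drop"
  )
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$timestamp / 60,
                                    y = .data$value,
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~week, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Hours since session start", y = channel,
                  colour = "Group") +
    ggplot2::theme_minimal()
}
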