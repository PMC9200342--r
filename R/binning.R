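#' Split animal-week records into contiguous bins
#'
#' Each animal-week record (290 samples by default) is cut into `n_bins`
#' contiguous, non-overlapping segments that together cover the whole record
#' in order; the bin is the unit of classification. When the record length is
#' not divisible by `n_bins`, the remainder samples are assigned one each to
#' the earliest bins (290 over 6 bins gives lengths 49, 49, 48, 48, 48, 48).
#' Each bin carries the integer class of its animal's group: naive 0,
#' injured 1, sham 2.
#'
#' @param cohort Cohort tibble (see [simulate_cohort()] / [read_hca_csv()]).
#' @param n_bins Number of bins per animal-week, between 1 and 20 (default 6).
#' @return A tibble with one row per bin: `animal_id`, `group`, `week`,
#'   `bin` (0-based), `label` (0/1/2) and a `segment` list-column of
#'   per-sample tibbles (`timestamp` + the four channels).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 1))
#' bins <- bin_observations(cohort, n_bins = 6)
#' dplyr::count(bins, label)
bin_observations <- function(cohort, n_bins = 6) {
  if (n_bins < 1 || n_bins > 20) abort("`n_bins` must be between 1 and 20.")
  n_bins <- as.integer(n_bins)
  recs <- dplyr::group_split(
    dplyr::group_by(cohort, .data$animal_id, .data$group, .data$week)
  )
  purrr::list_rbind(purrr::map(recs, function(rec) {
    rec <- dplyr::arrange(rec, .data$timestamp)
    len <- nrow(rec)
    if (len < n_bins) {
      abort(paste0("Record ", rec$animal_id[1], " week ", rec$week[1],
                   " has ", len, " samples; cannot form ", n_bins, " bins."))
    }
    sizes <- bin_sizes(len, n_bins)
    stops <- cumsum(sizes)
    starts <- c(1L, head(stops, -1) + 1L)
    tibble::tibble(
      animal_id = rec$animal_id[1],
      group = rec$group[1],
      week = rec$week[1],
      bin = 0:(n_bins - 1L),
      label = group_to_class(rec$group[1]),
      segment = purrr::map2(starts, stops, function(a, b) {
        rec[a:b, c("timestamp", hca_channels())]
      })
    )
  }))
}

# Equal-as-possible split: remainder spread one-each over the earliest bins.
bin_sizes <- function(len, n_bins) {
  base <- len %/% n_bins
  rem <- len %% n_bins
  rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
}

#' Per-bin mean features for the shallow classifiers
#'
#' Collapses each bin into a single data point: the arithmetic mean of each
#' of the four channels over the bin's samples. This record-style dataset is
#' what the SVM, random forest and feed-forward network consume.
#'
#' @param bins Binned observations from [bin_observations()].
#' @return A tibble with the provenance columns (`animal_id`, `group`,
#'   `week`, `bin`, `label`) and one mean column per channel.
#' @export
record_features <- function(bins) {
  if (any(purrr::map_int(bins$segment, nrow) == 0)) {
    abort("Empty bin segment encountered.")
  }
  means <- purrr::map(bins$segment, function(seg) {
    colMeans(as.matrix(seg[, hca_channels()]))
  })
  dplyr::bind_cols(
    bins[, c("animal_id", "group", "week", "bin", "label")],
    tibble::as_tibble(do.call(rbind, means))
  )
}

#' Sequence tensor for the deep classifier
#'
#' Keeps the full within-bin time course of every observation as a
#' `target_len` x 4 sequence. Segments shorter than `target_len` are padded
#' with zeros at the end; longer segments are truncated at the end. The
#' returned mask marks real (unpadded) positions.
#'
#' @param bins Binned observations from [bin_observations()].
#' @param target_len Common sequence length (default 48).
#' @return An object of class `hc_sequences`: a list with `data` (an
#'   N x `target_len` x 4 array), `mask` (N x `target_len` logical matrix,
#'   `TRUE` for real samples), `labels` (length-N integer vector) and `index`
#'   (tibble of provenance columns).
#' @export
sequence_features <- function(bins, target_len = 48) {
  if (target_len < 1) abort("`target_len` must be >= 1.")
  target_len <- as.integer(target_len)
  n <- nrow(bins)
  data <- array(0, dim = c(n, target_len, 4L),
                dimnames = list(NULL, NULL, hca_channels()))
  mask <- matrix(FALSE, n, target_len)
  for (i in seq_len(n)) {
    seg <- as.matrix(bins$segment[[i]][, hca_channels()])
    keep <- min(nrow(seg), target_len)
    data[i, seq_len(keep), ] <- seg[seq_len(keep), ]
    mask[i, seq_len(keep)] <- TRUE
  }
  structure(
    list(
      data = data, mask = mask,
      labels = as.integer(bins$label),
      index = bins[, c("animal_id", "group", "week", "bin", "label")]
    ),
    class = "hc_sequences"
  )
}

#' @export
print.hc_sequences <- function(x, ...) {
  cat("<hc_sequences> ", dim(x$data)[1], " sequences x ", dim(x$data)[2],
      " steps x ", dim(x$data)[3], " channels (",
      sum(!x$mask), " padded positions)\n", sep = "")
  invisible(x)
}

# Row subset of a sequence set (used by the cross-validation folds).
subset_sequences <- function(seqs, idx) {
  structure(
    list(
      data = seqs$data[idx, , , drop = FALSE],
      mask = seqs$mask[idx, , drop = FALSE],
      labels = seqs$labels[idx],
      index = seqs$index[idx, ]
    ),
    class = "hc_sequences"
  )
}
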