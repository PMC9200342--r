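#' The HCA CSV dialect
#'
#' One comma-separated, UTF-8, headered row per (animal, timestamp), with the
#' fixed column set `animal_id, group, week, timestamp, distance_mm,
#' temperature_c, separation_mm, transitions`. Timestamps are minutes since
#' session start on the 15-minute grid. Vendor exports with different column
#' names can be ingested through the `column_map` argument of
#' [read_hca_csv()].
#'
#' @return Character vector of the required column names, in order.
#' @export
hca_csv_columns <- function() {
  c("animal_id", "group", "week", "timestamp", hca_channels())
}

#' Read an HCA-style behavioural CSV
#'
#' Parses the dialect described in [hca_csv_columns()], validating the column
#' set, numeric channel values and (animal, week, timestamp) uniqueness. Rows
#' are returned sorted by animal, week and timestamp regardless of their order
#' on disk, so each animal-week forms one contiguous, time-ordered record.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector mapping names *found in
#'   the file* to dialect names, e.g. `c(Distance = "distance_mm")`, used to
#'   ingest a vendor export's native header.
#' @return A cohort tibble (same shape as [simulate_cohort()] output).
#' @export
read_hca_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(column_map)) {
    hit <- names(column_map) %in% names(raw)
    names(raw)[match(names(column_map)[hit], names(raw))] <- column_map[hit]
  }
  missing <- setdiff(hca_csv_columns(), names(raw))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  raw <- raw[, hca_csv_columns()]
  for (col in c("week", "timestamp", hca_channels())) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(paste0("Non-numeric value in column `", col, "` at data row ",
                   bad[1], ": ", raw[[col]][bad[1]]))
    }
    if (anyNA(parsed)) {
      abort(paste0("Missing value in column `", col, "`."))
    }
    raw[[col]] <- parsed
  }
  raw$week <- as.integer(raw$week)
  dup <- duplicated(raw[, c("animal_id", "week", "timestamp")])
  if (any(dup)) {
    d <- raw[which(dup)[1], ]
    abort(paste0("Duplicate (animal, week, timestamp): ", d$animal_id,
                 ", week ", d$week, ", t = ", d$timestamp))
  }
  dplyr::arrange(raw, .data$animal_id, .data$week, .data$timestamp)
}

#' Write a cohort to an HCA-style CSV
#'
#' Writes one row per sample in the deterministic order (animal, week,
#' timestamp) so that write-read-write round trips are byte-identical.
#' Numeric values are serialised at full double precision.
#'
#' @param cohort Cohort tibble (see [simulate_cohort()]).
#' @param path Output file path.
#' @return Invisibly, the number of rows written.
#' @export
write_hca_csv <- function(cohort, path) {
  if (nrow(cohort) == 0) abort("Refusing to write an empty cohort.")
  missing <- setdiff(hca_csv_columns(), names(cohort))
  if (length(missing) > 0) {
    abort(paste0("Cohort lacks column(s): ", paste(missing, collapse = ", ")))
  }
  out <- dplyr::arrange(cohort[, hca_csv_columns()],
                        .data$animal_id, .data$week, .data$timestamp)
  readr::write_csv(out, path, progress = FALSE)
  invisible(nrow(out))
}
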