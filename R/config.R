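#' Read a plain-text key = value configuration file
#'
#' Minimal run-configuration format used by the command-line entry point:
#' one `key = value` pair per line, `#` comments and blank lines ignored.
#' Values are parsed as numeric where possible, comma-separated values become
#' vectors, everything else stays character.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(paste0("Malformed config line (expected key = value): ", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' Write a run manifest next to outputs
#'
#' Records the effective configuration, seed and package version of a run as
#' JSON, so every artifact directory documents exactly how it was produced.
#'
#' @param dir Output directory (created if absent).
#' @param config Named list of effective settings.
#' @param seed Integer seed of the run.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(dir, config, seed) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(
    package = "hcaclassify",
    version = as.character(utils::packageVersion("hcaclassify")),
    seed = seed,
    config = config,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
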