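# Delimited-text persistence for fluorescence matrices, event tables and
# simulation configs. Matrices are TSV with neurons in rows and frames in
# columns; a JSON sidecar (or header comment) carries the sampling period
# and metadata.

#' Write a fluorescence matrix as delimited text
#'
#' Neurons in rows, frames in columns; metadata (`sampling_period_s`,
#' network/plate/cell-line ids, diagnosis) in `#`-prefixed header lines.
#'
#' @param fm a [fluorescence_matrix()].
#' @param path output file path (TSV).
#' @return `path`, invisibly.
#' @export
write_fluorescence <- function(fm, path) {
  stopifnot(inherits(fm, "fluorescence_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(sampling_period_s = fm$sampling_period_s,
            network_id = fm$network_id, plate_id = fm$plate_id,
            cell_line_id = fm$cell_line_id, diagnosis = fm$diagnosis)
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.table(fm$values, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fluorescence matrix written by [write_fluorescence()]
#'
#' Plain numeric TSV files without the metadata header are accepted too;
#' they get default metadata and `sampling_period_s = 0.1506`.
#'
#' @param path file path.
#' @return a [fluorescence_matrix()].
#' @export
read_fluorescence <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in header) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:\\s*", "", kv))
  }
  body <- lines[!grepl("^#", lines)]
  values <- as.matrix(utils::read.table(text = body, sep = "\t"))
  fluorescence_matrix(
    values,
    sampling_period_s = as.numeric(meta$sampling_period_s %||% 0.1506),
    network_id = meta$network_id %||% basename(path),
    plate_id = meta$plate_id %||% "plate1",
    cell_line_id = meta$cell_line_id %||% "line1",
    diagnosis = meta$diagnosis %||% "HC")
}

#' Read a simulation-cohort configuration from JSON
#'
#' The file holds either a single config object or an array of them; fields
#' match [sim_config()] arguments.
#'
#' @param path JSON file path.
#' @return list of [sim_config()] objects.
#' @export
read_sim_configs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(names(raw))) raw <- list(raw)
  lapply(raw, function(cfg) do.call(sim_config, cfg))
}

#' Write an event table as delimited text
#'
#' @param events event data frame from [detect_events_network()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
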