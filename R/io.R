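#' Write / read a single ECG record as CSV
#'
#' Plain two-column CSV (`sample_index` 0-based, `voltage_mV`) with a
#' WFDB-style sidecar header `<record_id>.hea` carrying record id, sample
#' count, sampling rate and label; true R indices (synthetic records) go
#' in a third sidecar column file so round-trips are lossless.
#'
#' @param record An `ecg_record`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the CSV path.
#' @export
write_record <- function(record, dir) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(record$record_id, ".csv"))
  utils::write.csv(data.frame(sample_index = seq_along(record$samples) - 1L,
                              voltage_mV = record$samples),
                   csv, row.names = FALSE)
  hea <- file.path(dir, paste0(record$record_id, ".hea"))
  writeLines(c(sprintf("%s 1 %g %d", record$record_id, record$fs,
                       length(record$samples)),
               sprintf("# label %s", record$label),
               sprintf("# true_r_indices %s",
                       paste(record$true_r_indices, collapse = " "))),
             hea)
  invisible(csv)
}

#' @rdname write_record
#' @param record_id Record to read back.
#' @export
read_record <- function(dir, record_id) {
  csv <- file.path(dir, paste0(record_id, ".csv"))
  hea <- file.path(dir, paste0(record_id, ".hea"))
  df <- utils::read.csv(csv)
  lines <- readLines(hea)
  fs <- as.numeric(strsplit(lines[1], " ")[[1]][3])
  label <- sub("^# label ", "", lines[2])
  rtxt <- sub("^# true_r_indices ?", "", lines[3])
  ri <- if (nzchar(rtxt)) as.integer(strsplit(rtxt, " ")[[1]]) else integer(0)
  structure(list(record_id = record_id, samples = df$voltage_mV, fs = fs,
                 label = label, true_r_indices = ri),
            class = "ecg_record")
}

#' Write a dataset (records + JSON manifest) to a directory
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in dataset$records) write_record(rec, dir)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(dataset$manifest, manifest, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write / read a beat-window matrix as CSV
#'
#' One row per window: record_id, r_index, label, then the sample columns.
#'
#' @param beats A `beat_windows` object.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_windows <- function(beats, path) {
  stopifnot(inherits(beats, "beat_windows"))
  w <- as.data.frame(beats$windows)
  names(w) <- sprintf("s%03d", seq_len(ncol(w)))
  utils::write.csv(cbind(beats$meta, w), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  scols <- grep("^s\\d+$", names(df))
  structure(list(windows = as.matrix(df[, scols]),
                 meta = df[, c("record_id", "r_index", "label")]),
            class = "beat_windows")
}
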