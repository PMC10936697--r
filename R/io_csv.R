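#' Export a recording to delimited text
#'
#' Writes one `time_s` column (seconds from record start) plus one column
#' per channel. Annotations go to a tab-separated sidecar
#' `<stem>_annotations.tsv` (`time_s`, `kind`, `label`; one line per
#' annotation, no header), written only when annotations exist.
#'
#' @param record a [signal_record()].
#' @param path output `.csv` file.
#' @return invisibly, `path`.
#' @export
export_csv <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  n <- nrow(record$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / record$fs)
  for (j in seq_len(ncol(record$samples))) {
    df[[record$channel_labels[j]]] <- record$samples[, j]
  }
  utils::write.csv(df, path, row.names = FALSE)
  if (nrow(record$annotations)) {
    a <- record$annotations
    utils::write.table(a[c("time_s", "kind", "label")], csv_sidecar(path),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

csv_sidecar <- function(path) {
  paste0(sub("\\.csv$", "", path, ignore.case = TRUE), "_annotations.tsv")
}

#' Read a delimited-text recording
#'
#' Expects the [export_csv()] layout; the sampling rate is inferred from the
#' median time step and annotations are picked up from the sidecar when
#' present.
#'
#' @param path `.csv` file path.
#' @return A [signal_record()].
#' @export
read_csv_record <- function(path) {
  if (!file.exists(path)) stop_regwave("file not found: ", path)
  df <- utils::read.csv(path)
  if (names(df)[1] != "time_s" || ncol(df) < 2) {
    stop_regwave("expected a time_s column followed by channel columns in ",
                 path)
  }
  dt <- stats::median(diff(df$time_s))
  if (!is.finite(dt) || dt <= 0) stop_regwave("cannot infer sampling rate from ",
                                              path)
  ann <- annotations_frame()
  side <- csv_sidecar(path)
  if (file.exists(side) && file.size(side) > 0) {
    a <- utils::read.table(side, sep = "\t", header = FALSE,
                           col.names = c("time_s", "kind", "label"),
                           stringsAsFactors = FALSE)
    ann <- annotations_frame(a$time_s, a$label, a$kind)
  }
  signal_record(as.matrix(df[-1]), fs = 1 / dt,
                channel_labels = names(df)[-1], annotations = ann)
}
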