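# Native storage dialect
#
# A recording is stored as two files sharing a stem: <stem>.rwf holds the
# waveform, <stem>.meta the setup information and annotations.
#
# .rwf layout (all little-endian):
#   bytes 0-7   magic "REGWAVE1"
#   int32       format version (1)
#   int32       n_channels
#   float64     fs (Hz)
#   int32       n_samples per channel
#   float32 x (n_samples * n_channels)  channel-interleaved samples
#                (sample 0 ch 0, sample 0 ch 1, ..., sample 1 ch 0, ...)
#
# .meta layout: ASCII "key=value" lines, then a "[annotations]" marker, then
# one line per annotation: time_s<TAB>kind<TAB>label. Unknown keys are
# preserved on read as opaque metadata.

RWF_MAGIC <- "REGWAVE1"
RWF_VERSION <- 1L

native_paths <- function(path) {
  stem <- sub("\\.(rwf|meta)$", "", path)
  list(rwf = paste0(stem, ".rwf"), meta = paste0(stem, ".meta"))
}

#' Write a recording in the native binary+metafile dialect
#'
#' Samples are stored as little-endian 32-bit floats (channel-interleaved)
#' behind a fixed magic string and header; setup information and annotations
#' go to an ASCII metafile next to the binary. See the package vignette for
#' the byte-level layout.
#'
#' @param record a [signal_record()].
#' @param path output stem (with or without the `.rwf` extension); writes
#'   `<stem>.rwf` and `<stem>.meta`.
#' @return invisibly, the two paths written.
#' @seealso [read_record()]
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  p <- native_paths(path)
  n <- nrow(record$samples)
  nc <- ncol(record$samples)
  con <- file(p$rwf, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(RWF_MAGIC, con, nchars = 8, eos = NULL)
  writeBin(RWF_VERSION, con, size = 4, endian = "little")
  writeBin(as.integer(nc), con, size = 4, endian = "little")
  writeBin(as.numeric(record$fs), con, size = 8, endian = "little")
  writeBin(as.integer(n), con, size = 4, endian = "little")
  writeBin(as.numeric(t(record$samples)), con, size = 4, endian = "little")

  lines <- c(
    paste0("format=regwave-meta"),
    paste0("version=", RWF_VERSION),
    paste0("n_channels=", nc),
    paste0("fs=", format(record$fs, digits = 15)),
    paste0("n_samples=", n),
    paste0("start_time=", format(record$start_time, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC")),
    paste0("channel_labels=", paste(record$channel_labels, collapse = ",")),
    paste0("channel_units=", paste(record$channel_units, collapse = ",")))
  if (length(record$metadata)) {
    lines <- c(lines, paste0(names(record$metadata), "=",
                             vapply(record$metadata, as.character, "")))
  }
  lines <- c(lines, "[annotations]")
  if (nrow(record$annotations)) {
    a <- record$annotations
    lines <- c(lines, sprintf("%s\t%s\t%s", format(a$time_s, digits = 15),
                              a$kind, a$label))
  }
  writeLines(lines, p$meta)
  invisible(c(p$rwf, p$meta))
}

#' Read a recording
#'
#' Dispatches on the file extension: `.edf` via the EDF reader, `.csv` via
#' the delimited-text reader, anything else as the native binary+metafile
#' dialect. Native reads are loud about malformed input: a bad magic string
#' or version raises a format error, and a truncated payload raises an error
#' naming the expected and found sample counts.
#'
#' @param path file path (native stem, `.rwf`, `.edf` or `.csv`).
#' @return A [signal_record()].
#' @export
read_record <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(read_edf(path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(read_csv_record(path))
  p <- native_paths(path)
  if (!file.exists(p$rwf)) stop_regwave("file not found: ", p$rwf)
  con <- file(p$rwf, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readChar(con, 8, useBytes = TRUE)
  if (!identical(magic, RWF_MAGIC)) {
    stop_regwave("not a native waveform file (bad magic string in ", p$rwf, ")")
  }
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(version, RWF_VERSION)) {
    stop_regwave("unsupported native format version ", version)
  }
  nc <- readBin(con, "integer", 1, size = 4, endian = "little")
  fs <- readBin(con, "numeric", 1, size = 8, endian = "little")
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  expected <- n * nc
  x <- readBin(con, "numeric", expected, size = 4, endian = "little")
  if (length(x) < expected) {
    stop_regwave("truncated waveform payload in ", p$rwf, ": expected ",
                 expected, " samples, found ", length(x))
  }
  samples <- t(matrix(x, nrow = nc))

  if (!file.exists(p$meta)) stop_regwave("metafile not found: ", p$meta)
  lines <- readLines(p$meta)
  ann_at <- match("[annotations]", lines)
  if (is.na(ann_at)) ann_at <- length(lines) + 1
  kv_lines <- lines[seq_len(ann_at - 1)]
  kv_lines <- kv_lines[grepl("=", kv_lines, fixed = TRUE)]
  keys <- sub("=.*$", "", kv_lines)
  vals <- sub("^[^=]*=", "", kv_lines)
  meta <- stats::setNames(as.list(vals), keys)
  known <- c("format", "version", "n_channels", "fs", "n_samples",
             "start_time", "channel_labels", "channel_units")
  ann <- annotations_frame()
  if (!is.na(ann_at) && ann_at < length(lines)) {
    al <- lines[(ann_at + 1):length(lines)]
    al <- al[nzchar(al)]
    if (length(al)) {
      parts <- strsplit(al, "\t", fixed = TRUE)
      ann <- annotations_frame(
        time_s = as.numeric(vapply(parts, `[`, "", 1)),
        label = vapply(parts, `[`, "", 3),
        kind = vapply(parts, `[`, "", 2))
    }
  }
  labels <- strsplit(meta$channel_labels %||% "", ",")[[1]]
  if (length(labels) != nc) labels <- paste0("ch", seq_len(nc))
  units <- strsplit(meta$channel_units %||% "V", ",")[[1]]
  start_time <- as.POSIXct(meta$start_time %||% "2000-01-01T00:00:00Z",
                           format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  signal_record(samples, fs, labels, units, start_time, ann,
                metadata = meta[setdiff(names(meta), known)])
}
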