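# Minimal EDF (European Data Format) writer/reader covering the subset this
# pipeline needs: continuous recordings, one sampling rate shared by all
# channels, 1-second data records, 16-bit samples with per-channel physical
# scaling. Header fields are fixed-width ASCII per the EDF specification.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

# Format a physical bound into EDF's 8-char field and return the value the
# ASCII actually encodes, so writer and reader use identical scaling.
edf_phys <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= 8) break
  }
  if (nchar(s) > 8) stop_regwave("physical bound does not fit EDF field: ", x)
  list(text = edf_field(s, 8), value = as.numeric(s))
}

#' Export a recording to EDF
#'
#' Writes a continuous EDF file with 1-second data records and the
#' standard's 16-bit integer sample encoding. Physical minimum/maximum are
#' chosen per channel from the data range (a constant channel is padded by
#' one unit so the scale is non-degenerate), so a round trip reproduces each
#' sample within one quantization step of the 16-bit scaling. Channel labels
#' longer than the standard's 16-character field are truncated with a
#' warning. Annotations are not representable in plain EDF; export them with
#' [export_csv()]'s sidecar instead. A final partial second of samples is
#' dropped with a warning.
#'
#' @param record a [signal_record()]; `fs` must be a whole number.
#' @param path output `.edf` file.
#' @return invisibly, `path`.
#' @export
export_edf <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  fs <- record$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop_regwave("EDF export needs an integer sampling rate (1-s records)")
  }
  fs <- as.integer(round(fs))
  n <- nrow(record$samples)
  nc <- ncol(record$samples)
  n_rec <- n %/% fs
  if (n_rec < 1) stop_regwave("record shorter than one EDF data record (1 s)")
  if (n_rec * fs < n) {
    warning("EDF export dropped a final partial second (",
            n - n_rec * fs, " samples)")
  }
  labels <- record$channel_labels
  too_long <- nchar(labels) > 16
  if (any(too_long)) {
    warning("channel label(s) truncated to 16 characters for EDF: ",
            paste(labels[too_long], collapse = ", "))
    labels[too_long] <- substr(labels[too_long], 1, 16)
  }

  dmin <- -32768; dmax <- 32767
  pmin <- numeric(nc); pmax <- numeric(nc)
  pmin_txt <- character(nc); pmax_txt <- character(nc)
  for (j in seq_len(nc)) {
    lo <- min(record$samples[, j]); hi <- max(record$samples[, j])
    if (lo == hi) { lo <- lo - 1; hi <- hi + 1 }
    lo_f <- edf_phys(lo); hi_f <- edf_phys(hi)
    # widen to the encoded values so every sample stays inside the range
    if (lo_f$value > lo) lo_f <- edf_phys(lo - abs(lo) * 1e-5 - 1e-12)
    if (hi_f$value < hi) hi_f <- edf_phys(hi + abs(hi) * 1e-5 + 1e-12)
    pmin[j] <- lo_f$value; pmax[j] <- hi_f$value
    pmin_txt[j] <- lo_f$text; pmax_txt[j] <- hi_f$text
  }

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(edf_field("0", 8))                                   # version
  wr(edf_field("X X X X", 80))                            # patient id
  wr(edf_field("Startdate X X X X", 80))                  # recording id
  wr(edf_field(format(record$start_time, "%d.%m.%y", tz = "UTC"), 8))
  wr(edf_field(format(record$start_time, "%H.%M.%S", tz = "UTC"), 8))
  wr(edf_field(256 + 256 * nc, 8))                        # header bytes
  wr(edf_field("", 44))                                   # reserved
  wr(edf_field(n_rec, 8))
  wr(edf_field(1, 8))                                     # record duration s
  wr(edf_field(nc, 4))
  for (s in labels) wr(edf_field(s, 16))
  for (j in seq_len(nc)) wr(edf_field("", 80))            # transducer
  for (j in seq_len(nc)) wr(edf_field(record$channel_units[j], 8))
  for (j in seq_len(nc)) wr(pmin_txt[j])
  for (j in seq_len(nc)) wr(pmax_txt[j])
  for (j in seq_len(nc)) wr(edf_field(dmin, 8))
  for (j in seq_len(nc)) wr(edf_field(dmax, 8))
  for (j in seq_len(nc)) wr(edf_field("", 80))            # prefiltering
  for (j in seq_len(nc)) wr(edf_field(fs, 8))             # samples per record
  for (j in seq_len(nc)) wr(edf_field("", 32))            # reserved

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(nc)) {
      dig <- round((record$samples[idx, j] - pmin[j]) * scale[j]) + dmin
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads continuous EDF recordings in which every channel shares one
#' sampling rate. Samples are rescaled to physical units from the
#' per-channel 16-bit scaling.
#'
#' @param path `.edf` file path.
#' @return A [signal_record()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_regwave("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rd(8))
  if (version != "0") stop_regwave("not an EDF file (version field '",
                                   version, "')")
  rd(80); rd(80)                                          # patient, recording
  date_s <- trimws(rd(8)); time_s <- trimws(rd(8))
  rd(8)                                                   # header bytes
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  nc <- as.integer(trimws(rd(4)))
  labels <- trimws(vapply(seq_len(nc), function(j) rd(16), ""))
  vapply(seq_len(nc), function(j) rd(80), "")
  units <- trimws(vapply(seq_len(nc), function(j) rd(8), ""))
  pmin <- as.numeric(vapply(seq_len(nc), function(j) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(nc), function(j) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nc), function(j) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nc), function(j) rd(8), ""))
  vapply(seq_len(nc), function(j) rd(80), "")
  spr <- as.integer(vapply(seq_len(nc), function(j) rd(8), ""))
  vapply(seq_len(nc), function(j) rd(32), "")
  if (length(unique(spr)) != 1) {
    stop_regwave("EDF files with per-channel sampling rates are not supported")
  }
  fs <- spr[1] / rec_dur
  samples <- matrix(0, nrow = n_rec * spr[1], ncol = nc)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(nc)) {
      dig <- readBin(con, "integer", spr[j], size = 2, endian = "little",
                     signed = TRUE)
      if (length(dig) < spr[j]) {
        stop_regwave("truncated EDF payload: expected ", spr[j],
                     " samples in record ", r, ", found ", length(dig))
      }
      idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
      samples[idx, j] <- pmin[j] +
        (dig - dmin[j]) * (pmax[j] - pmin[j]) / (dmax[j] - dmin[j])
    }
  }
  start_time <- as.POSIXct(paste(date_s, time_s),
                           format = "%d.%m.%y %H.%M.%S", tz = "UTC")
  if (is.na(start_time)) {
    start_time <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  }
  signal_record(samples, fs, labels, units, start_time)
}
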