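#' Multichannel uniformly sampled waveform recording
#'
#' `signal_record` is the pipeline's universal currency: a samples-by-channels
#' numeric matrix with a sampling rate, per-channel labels and units, a start
#' timestamp, and a table of time-stamped annotations (event markers, text
#' notes, blood-pressure readings). Channel amplitudes are kept in acquisition
#' units; REG pulse waves are typically in volts or raw analog-to-digital
#' counts, and all morphology statistics downstream are relative (percent of
#' baseline), so the absolute unit never enters a result.
#'
#' @param samples numeric matrix, one row per sample and one column per
#'   channel (a plain vector is treated as a single channel).
#' @param fs sampling rate in Hz; must be positive.
#' @param channel_labels character vector, one label per channel.
#' @param channel_units character vector recycled across channels
#'   (default `"V"`).
#' @param start_time `POSIXct` timestamp of sample 0.
#' @param annotations data frame as returned by [annotations_frame()].
#' @param metadata named list of opaque key-value metadata carried through
#'   file round trips.
#'
#' @return An object of class `signal_record`.
#' @seealso [annotations_frame()], [write_record()], [generate_session()]
#' @examples
#' rec <- signal_record(cbind(head = sin(seq(0, 2 * pi, length.out = 200))),
#'                      fs = 200)
#' duration_s(rec)
#' @export
signal_record <- function(samples, fs,
                          channel_labels = NULL,
                          channel_units = "V",
                          start_time = as.POSIXct("2000-01-01 00:00:00", tz = "UTC"),
                          annotations = annotations_frame(),
                          metadata = list()) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop_regwave("`samples` must be a numeric matrix (samples x channels)")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop_regwave("`fs` must be a single positive number (Hz)")
  }
  nc <- ncol(samples)
  if (is.null(channel_labels)) {
    channel_labels <- colnames(samples) %||% paste0("ch", seq_len(nc))
  }
  if (length(channel_labels) != nc) {
    stop_regwave("need one channel label per channel (", nc, " channels)")
  }
  channel_units <- rep_len(channel_units, nc)
  colnames(samples) <- channel_labels
  rec <- structure(
    list(samples = samples, fs = fs,
         channel_labels = as.character(channel_labels),
         channel_units = as.character(channel_units),
         start_time = start_time,
         annotations = validate_annotations(annotations),
         metadata = metadata),
    class = "signal_record")
  dur <- nrow(samples) / fs
  if (nrow(rec$annotations) && any(rec$annotations$time_s > dur + 1e-9)) {
    stop_regwave("annotation times must lie within the recording [0, ",
                 format(dur), "] s")
  }
  rec
}

#' Build an annotation table
#'
#' @param time_s numeric, seconds from record start (must be >= 0).
#' @param label character, non-empty annotation text.
#' @param kind one of `"EVENT_MARKER"`, `"NOTE"`, `"BP_READING"`.
#' @return data frame with columns `time_s`, `label`, `kind`.
#' @export
annotations_frame <- function(time_s = numeric(0), label = character(0),
                              kind = character(0)) {
  if (!length(kind)) kind <- rep("EVENT_MARKER", length(time_s))
  validate_annotations(
    data.frame(time_s = as.numeric(time_s), label = as.character(label),
               kind = as.character(kind), stringsAsFactors = FALSE))
}

annotation_kinds <- c("EVENT_MARKER", "NOTE", "BP_READING")

validate_annotations <- function(ann) {
  if (!is.data.frame(ann) || !all(c("time_s", "label", "kind") %in% names(ann))) {
    stop_regwave("annotations must be a data frame with time_s, label, kind")
  }
  if (nrow(ann)) {
    if (any(ann$time_s < 0)) stop_regwave("annotation times must be >= 0")
    if (any(!nzchar(ann$label))) stop_regwave("annotation labels must be non-empty")
    if (any(!ann$kind %in% annotation_kinds)) {
      stop_regwave("annotation kind must be one of ",
                   paste(annotation_kinds, collapse = ", "))
    }
  }
  ann[c("time_s", "label", "kind")]
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d channels x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), nrow(x$samples), x$fs, duration_s(x)))
  cat("  channels:",
      paste(sprintf("%s [%s]", x$channel_labels, x$channel_units),
            collapse = ", "), "\n")
  cat(sprintf("  annotations: %d\n", nrow(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param record a [signal_record()].
#' @return numeric scalar.
#' @export
duration_s <- function(record) nrow(record$samples) / record$fs

#' Number of channels in a recording
#' @param record a [signal_record()].
#' @return integer scalar.
#' @export
n_channels <- function(record) ncol(record$samples)

#' Extract one channel as a numeric vector
#' @param record a [signal_record()].
#' @param channel channel label or index.
#' @return numeric vector of samples.
#' @export
get_channel <- function(record, channel) {
  idx <- resolve_channel(record, channel)
  record$samples[, idx]
}

resolve_channel <- function(record, channel) {
  if (is.character(channel)) {
    idx <- match(channel, record$channel_labels)
    if (is.na(idx)) {
      stop_regwave("no channel named '", channel, "' (have: ",
                   paste(record$channel_labels, collapse = ", "), ")")
    }
    return(idx)
  }
  channel <- as.integer(channel)
  if (channel < 1 || channel > n_channels(record)) {
    stop_regwave("channel index out of range")
  }
  channel
}

#' Append annotations to a recording
#' @param record a [signal_record()].
#' @param time_s,label,kind vectors passed to [annotations_frame()].
#' @return the modified record.
#' @export
add_annotations <- function(record, time_s, label, kind = "EVENT_MARKER") {
  extra <- annotations_frame(time_s, label, rep_len(kind, length(time_s)))
  ann <- rbind(record$annotations, extra)
  ann <- ann[order(ann$time_s), , drop = FALSE]
  rownames(ann) <- NULL
  signal_record(record$samples, record$fs, record$channel_labels,
                record$channel_units, record$start_time, ann, record$metadata)
}

#' Plot a recording
#'
#' Stacked per-channel traces with annotation times marked.
#'
#' @param x a [signal_record()].
#' @param channels channels to draw (default all).
#' @param xlim optional time range in seconds.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.signal_record <- function(x, channels = x$channel_labels, xlim = NULL, ...) {
  t <- seq_len(nrow(x$samples)) / x$fs
  old <- graphics::par(mfrow = c(length(channels), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ch in channels) {
    y <- get_channel(x, ch)
    graphics::plot(t, y, type = "l", xlab = "time (s)", ylab = ch,
                   xlim = xlim, ...)
    if (nrow(x$annotations)) {
      graphics::abline(v = x$annotations$time_s, col = "grey60", lty = 3)
    }
  }
  invisible(x)
}
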