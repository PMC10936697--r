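#' Segment a channel into beats
#'
#' Beats are delimited by successive pulse-wave minima (onsets), mirroring the
#' cursor-to-minimum convention used when reading REG pulse waves by hand.
#' Candidate onsets are prominent local minima; a refractory period of
#' `60 / hr_bounds_bpm[2]` seconds suppresses intra-beat notches (deepest
#' minima win), and consecutive onset pairs whose implied RR interval falls
#' outside the physiologic heart-rate bounds are discarded. When an
#' [artifact_mask()] is supplied, beats overlapping a masked interval are
#' dropped.
#'
#' @param record a smoothed [signal_record()].
#' @param channel channel label or index.
#' @param hr_bounds_bpm admissible heart-rate range, beats per minute.
#' @param mask optional [artifact_mask()].
#' @param min_prominence_frac minimum onset prominence as a fraction of the
#'   channel's 5th-to-95th percentile amplitude.
#' @return data frame with one row per beat: `onset_index`, `end_index`
#'   (1-based sample indices), `onset_s`, `end_s`, `onset_value`. A flat
#'   signal yields zero rows, not an error. The channel is carried in
#'   `attr(, "channel")`.
#' @export
segment_beats <- function(record, channel, hr_bounds_bpm = c(40, 180),
                          mask = NULL, min_prominence_frac = 0.3) {
  x <- get_channel(record, channel)
  fs <- record$fs
  empty <- data.frame(onset_index = integer(0), end_index = integer(0),
                      onset_s = numeric(0), end_s = numeric(0),
                      onset_value = numeric(0))
  attr(empty, "channel") <- channel
  amp <- diff(stats::quantile(x, c(0.05, 0.95), names = FALSE))
  if (amp <= 0) return(empty)
  cand <- local_minima(x, min_prominence = min_prominence_frac * amp)
  if (length(cand) < 2) return(empty)
  # boundary samples may start/close a beat; admit them as candidates
  cand <- sort(unique(c(1L, cand, length(x))))
  refractory <- fs * 60 / hr_bounds_bpm[2]
  onsets <- enforce_min_distance(cand, -x[cand], refractory)
  if (length(onsets) < 2) return(empty)
  # onsets sit near the diastolic floor; drop candidates (typically at the
  # record edges or intra-beat notches) stranded far above their neighbours.
  # A running median detrends slow baseline drift before the outlier test.
  ov <- x[onsets]
  trend <- if (length(ov) >= 21) stats::runmed(ov, 21) else stats::median(ov)
  dev <- ov - trend
  onsets <- onsets[dev <= max(5 * stats::mad(dev), 0.05 * amp)]
  if (length(onsets) < 2) return(empty)
  rr <- diff(onsets) / fs
  ok <- rr >= 60 / hr_bounds_bpm[2] & rr <= 60 / hr_bounds_bpm[1]
  beats <- data.frame(onset_index = onsets[-length(onsets)][ok],
                      end_index = onsets[-1][ok])
  beats$onset_s <- (beats$onset_index - 1) / fs
  beats$end_s <- (beats$end_index - 1) / fs
  beats$onset_value <- x[beats$onset_index]
  if (!is.null(mask) && nrow(mask$intervals)) {
    drop <- rep(FALSE, nrow(beats))
    for (i in seq_len(nrow(mask$intervals))) {
      drop <- drop | (beats$onset_s < mask$intervals$end_s[i] &
                        beats$end_s > mask$intervals$start_s[i])
    }
    beats <- beats[!drop, , drop = FALSE]
  }
  rownames(beats) <- NULL
  attr(beats, "channel") <- channel
  beats
}

#' Per-beat pulse-wave morphology
#'
#' Extracts the three-peak morphology of one beat: P1 (percussion), P2
#' (tidal) and P3 (dicrotic) amplitudes and latencies, anacrotic time
#' (onset-to-P1), catacrotic shoulder, and the intracranial-compliance
#' morphology class. Candidate peaks are the beat's local maxima (plateaus
#' resolve to their first sample); P1 is the first maximum after onset, P2
#' the next — or, when no distinct P2 maximum exists, the derivative-defined
#' shoulder location so P2 statistics remain computable — and P3 the next
#' after P2. Amplitudes are measured relative to the onset (minimum) value,
#' matching the min-to-max cursor procedure.
#'
#' @param record a smoothed [signal_record()].
#' @param beat one-row data frame from [segment_beats()] (or a list with
#'   `onset_index` and `end_index`).
#' @param channel channel label; defaults to the channel recorded in the
#'   `beat`'s parent segmentation if present.
#' @param min_prominence_frac peak prominence floor as a fraction of the
#'   beat's amplitude range.
#' @return one-row data frame of class `pulse_features`: `p1_amp`, `p2_amp`,
#'   `p3_amp`, `p1_time_ms`, `p2_time_ms`, `p3_time_ms`, `anacrotic_ms`,
#'   `shoulder`, `fused`, `morph_class`, `p2_p1_ratio`, plus `onset_s` and
#'   `duration_ms`. Peaks that are absent are `NA`; a beat with no local
#'   maximum has all peaks `NA` and `morph_class` `NA` (flagged, never an
#'   error).
#' @export
extract_features <- function(record, beat, channel = NULL,
                             min_prominence_frac = 0.02) {
  channel <- channel %||% attr(beat, "channel")
  if (is.null(channel)) stop_regwave("supply `channel` (not recorded on beat)")
  x <- get_channel(record, channel)
  fs <- record$fs
  i0 <- beat$onset_index[1]
  i1 <- beat$end_index[1]
  if (i0 >= i1 || i1 > length(x)) stop_regwave("beat indices outside record")
  w <- x[i0:i1]
  rel <- w - w[1]
  rng <- diff(range(w))
  maxima <- local_maxima(w, min_prominence = min_prominence_frac * rng)
  maxima <- maxima[rel[maxima] > 0]
  out <- data.frame(onset_s = (i0 - 1) / fs,
                    duration_ms = (i1 - i0) / fs * 1000,
                    p1_amp = NA_real_, p2_amp = NA_real_, p3_amp = NA_real_,
                    p1_time_ms = NA_real_, p2_time_ms = NA_real_,
                    p3_time_ms = NA_real_, anacrotic_ms = NA_real_,
                    shoulder = FALSE, fused = FALSE,
                    morph_class = NA_character_, p2_p1_ratio = NA_real_)
  class(out) <- c("pulse_features", "data.frame")
  if (!length(maxima)) return(out)
  ms_of <- function(i) (i - 1) / fs * 1000
  p1 <- maxima[1]
  out$p1_amp <- rel[p1]
  out$p1_time_ms <- ms_of(p1)
  out$anacrotic_ms <- ms_of(p1)
  # a shoulder between P1 and the next distinct maximum means the tidal wave
  # did not resolve into its own peak: the next maximum is then P3, not P2
  sh <- detect_shoulder(w, p1, fs)
  if (sh$shoulder &&
      (length(maxima) < 2 || sh$location_ms < ms_of(maxima[2]))) {
    out$shoulder <- TRUE
    out$p2_amp <- rel[round(sh$location_ms / 1000 * fs) + 1]
    out$p2_time_ms <- sh$location_ms
    if (length(maxima) >= 2) {
      out$p3_amp <- rel[maxima[2]]
      out$p3_time_ms <- ms_of(maxima[2])
    }
  } else if (length(maxima) >= 2) {
    p2 <- maxima[2]
    out$p2_amp <- rel[p2]
    out$p2_time_ms <- ms_of(p2)
    if (length(maxima) >= 3) {
      out$p3_amp <- rel[maxima[3]]
      out$p3_time_ms <- ms_of(maxima[3])
    }
  } else {
    out$fused <- TRUE
  }
  if (!is.na(out$p1_amp) && !is.na(out$p2_amp) && out$p1_amp > 0) {
    out$p2_p1_ratio <- out$p2_amp / out$p1_amp
  }
  out$morph_class <- classify_morphology(out)
  out
}

#' Extract features for every beat of a channel
#'
#' Convenience wrapper: segments (unless `beats` is given) and runs
#' [extract_features()] per beat.
#'
#' @inheritParams segment_beats
#' @param beats optional precomputed result of [segment_beats()].
#' @return data frame with one `pulse_features` row per beat.
#' @export
extract_all_features <- function(record, channel, beats = NULL, mask = NULL) {
  if (is.null(beats)) beats <- segment_beats(record, channel, mask = mask)
  rows <- lapply(seq_len(nrow(beats)), function(k) {
    extract_features(record, beats[k, ], channel = channel)
  })
  if (!length(rows)) {
    f <- extract_features(
      signal_record(matrix(c(0, 1, 0), ncol = 1), fs = 1),
      list(onset_index = 1, end_index = 3), channel = 1)
    return(f[0, ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect a catacrotic shoulder
#'
#' A shoulder is an attenuated tidal (P2) wave that does not rise to a
#' distinct maximum: on the descending (catacrotic) limb after P1 the decay
#' decelerates and re-accelerates without the derivative ever turning
#' positive. Detection: smooth the first difference of the limb and look for
#' an interior local maximum of it at which the derivative is still negative;
#' if the derivative changes sign anywhere on the limb, the bump is a true
#' second peak and no shoulder is reported.
#'
#' @param beat_waveform numeric vector, one beat starting at its onset.
#' @param p1_index sample index of P1 within `beat_waveform`.
#' @param fs sampling rate in Hz.
#' @param min_prominence_frac prominence floor for the derivative bump,
#'   relative to the limb's peak decay rate.
#' @return list with `shoulder` (logical) and `location_ms` (ms from beat
#'   onset; `NA` when no shoulder).
#' @export
detect_shoulder <- function(beat_waveform, p1_index, fs,
                            min_prominence_frac = 0.05) {
  w <- beat_waveform
  rel <- w - w[1]
  none <- list(shoulder = FALSE, location_ms = NA_real_)
  if (p1_index >= length(w) - 2) return(none)
  # descending limb: from P1 until the wave has decayed to 10% of P1 height
  stop_at <- which(rel < 0.1 * rel[p1_index] & seq_along(w) > p1_index)[1]
  if (is.na(stop_at)) stop_at <- length(w)
  seg <- p1_index:stop_at
  if (length(seg) < 5) return(none)
  d <- running_mean(diff(w[seg]), min(5, length(seg) - 1))
  dmax <- max(abs(d))
  if (dmax == 0) return(none)
  if (any(d > 0.02 * dmax)) return(none)  # sign change: a real P2, not a shoulder
  cand <- local_maxima(d, min_prominence = min_prominence_frac * dmax)
  cand <- cand[d[cand] < 0]
  if (!length(cand)) return(none)
  # d[k] is the difference w[seg][k+1] - w[seg][k]; place the shoulder at the
  # sample after the deceleration minimum
  loc <- seg[1] + cand[1]
  list(shoulder = TRUE, location_ms = (loc - 1) / fs * 1000)
}

#' Classify intracranial-compliance morphology
#'
#' `GOOD_ICC` when P1 exceeds P2 (normal buffering), `POOR_ICC` when P2
#' reaches or exceeds P1 (compromised compliance; ties break toward
#' pathology), and `TRIANGULAR` when the three sub-waves have fused into a
#' single broad hump with no resolvable P1/P2 separation — the most
#' compromised pattern.
#'
#' @param features a `pulse_features` row from [extract_features()], or any
#'   list providing `p1_amp`, `p2_amp`, `fused`.
#' @return character: `"GOOD_ICC"`, `"POOR_ICC"`, `"TRIANGULAR"`, or `NA`
#'   when P1 was not found.
#' @export
classify_morphology <- function(features) {
  p1 <- features$p1_amp
  if (is.null(p1) || is.na(p1)) return(NA_character_)
  if (isTRUE(features$fused)) return("TRIANGULAR")
  p2 <- features$p2_amp
  if (is.null(p2) || is.na(p2)) return("TRIANGULAR")
  if (p1 > p2) "GOOD_ICC" else "POOR_ICC"
}

#' Classify anacrotic time
#'
#' The anacrotic (rising) time — pulse-wave minimum to P1 maximum — reflects
#' arterial elasticity; values at or beyond the 180 ms threshold are the
#' arteriosclerotic pattern.
#'
#' @param anacrotic_ms anacrotic time(s) in milliseconds (>= 0).
#' @param threshold_ms decision threshold (default 180 ms).
#' @return character vector: `"NORMAL"` (< threshold) or `"PROLONGED"`
#'   (>= threshold).
#' @examples
#' classify_anacrotic(87)   # NORMAL, a typical healthy value
#' classify_anacrotic(180)  # PROLONGED (boundary counts as prolonged)
#' @export
classify_anacrotic <- function(anacrotic_ms, threshold_ms = 180) {
  if (any(anacrotic_ms < 0, na.rm = TRUE)) {
    stop_regwave("anacrotic_ms must be >= 0")
  }
  ifelse(anacrotic_ms >= threshold_ms, "PROLONGED", "NORMAL")
}

#' Amplitude change as percent of baseline (BL%)
#'
#' @param control_mean baseline mean amplitude (non-zero).
#' @param test_mean test-condition amplitude.
#' @return `100 * (test_mean - control_mean) / control_mean`.
#' @examples
#' baseline_percent(1.042, 1.208) # 15.93
#' @export
baseline_percent <- function(control_mean, test_mean) {
  if (any(control_mean == 0)) stop_regwave("control mean must be non-zero")
  100 * (test_mean - control_mean) / control_mean
}

#' Summarise pulse features over an epoch
#'
#' Arithmetic means of the P1 and P2 amplitudes over the beats of one
#' analysis epoch, each mean taken over the subset of beats in which that
#' peak was found (a shoulder-derived P2 counts as found).
#'
#' @param features data frame of `pulse_features` rows.
#' @return list: `mean_p1`, `mean_p2`, `n_p1`, `n_p2`, `n_beats`.
#' @export
summarize_epoch <- function(features) {
  if (!nrow(features) || all(is.na(features$p1_amp))) {
    stop_regwave("epoch has no beat with a detected P1")
  }
  p1 <- features$p1_amp[!is.na(features$p1_amp)]
  p2 <- features$p2_amp[!is.na(features$p2_amp)]
  list(mean_p1 = mean(p1), mean_p2 = if (length(p2)) mean(p2) else NA_real_,
       n_p1 = length(p1), n_p2 = length(p2), n_beats = nrow(features))
}
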