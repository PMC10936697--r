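#' Two-channel sine pair with optional phase inversion
#'
#' Reproduces the in-vitro demonstration of the moving-correlation index: a
#' function generator feeds the same sinusoid to a "head" and an "arm"
#' channel; over chosen intervals the head channel is inverted (multiplied by
#' -1, slow drift included), which flips the index from +1 to -1. A small slow
#' drift common to both channels is on by default so 10-second epoch means are
#' non-degenerate: without it every epoch mean of a fast sinusoid is ~0 and
#' the Pearson correlation is undefined.
#'
#' @param freq_hz sine frequency (must be below `fs/2`).
#' @param amplitude peak amplitude in volts.
#' @param fs sampling rate in Hz.
#' @param duration_s record length in seconds.
#' @param inversion_intervals list of `c(start_s, end_s)` intervals (within
#'   `[0, duration_s)`) over which the head channel is negated. A sample at
#'   time `t` is inverted when `start_s <= t < end_s`.
#' @param drift `list(freq_hz, amplitude)` slow additive modulation common to
#'   both channels, or `NULL` to disable.
#' @return A [signal_record()] with channels `head` and `arm` and one
#'   annotation per inversion boundary.
#' @examples
#' rec <- generate_sine_pair(10, 1, 200, 60)
#' all(get_channel(rec, "head") == get_channel(rec, "arm"))
#' @export
generate_sine_pair <- function(freq_hz = 10, amplitude = 1, fs = 200,
                               duration_s = 1500,
                               inversion_intervals = list(),
                               drift = list(freq_hz = 1 / 150, amplitude = 0.05)) {
  if (freq_hz >= fs / 2) stop_regwave("freq_hz must be below fs/2")
  for (iv in inversion_intervals) {
    if (length(iv) != 2 || iv[1] >= iv[2] || iv[1] < 0 || iv[2] > duration_s) {
      stop_regwave("inversion interval [", paste(iv, collapse = ", "),
                   "] outside the recording [0, ", duration_s, ")")
    }
  }
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  base <- amplitude * sin(2 * pi * freq_hz * tt)
  if (!is.null(drift)) {
    base <- base + drift$amplitude * sin(2 * pi * drift$freq_hz * tt)
  }
  head <- base
  for (iv in inversion_intervals) {
    sel <- tt >= iv[1] & tt < iv[2]
    head[sel] <- -head[sel]
  }
  ann_t <- unlist(inversion_intervals)
  ann <- if (length(ann_t)) {
    annotations_frame(ann_t,
                      rep(c("INVERSION_START", "INVERSION_END"),
                          length(inversion_intervals)))
  } else annotations_frame()
  signal_record(cbind(head = head, arm = base), fs,
                channel_units = "V", annotations = ann)
}

# Breath-hold amplitude gain profile: unity outside the response, a linear
# ramp from (start + latency) to the configured peak, then a linear recovery
# back to unity over `recovery_s`. Peaks default to 10 s after the hold ends;
# responses peaking during the hold are produced by a negative
# peak_after_end_s — both timings occur in practice. The ramp-and-turnover
# shape keeps the configured peak time identifiable from the rendered beats,
# which the ground-truth contract requires.
bh_gain_profile <- function(t, bh_events, recovery_s = 30) {
  g <- rep(1, length(t))
  for (i in seq_len(nrow(bh_events))) {
    ev <- bh_events[i, ]
    t0 <- ev$start_s + ev$response_latency_s
    tp <- ev$start_s + ev$duration_s + ev$peak_after_end_s
    if (tp <= t0) tp <- t0 + 1
    dg <- ev$amplitude_gain - 1
    up <- t >= t0 & t < tp
    g[up] <- g[up] + dg * (t[up] - t0) / (tp - t0)
    dn <- t >= tp & t < tp + recovery_s
    g[dn] <- g[dn] + dg * (1 - (t[dn] - tp) / recovery_s)
  }
  g
}

arm_beat_params <- function() {
  beat_template_params(p1 = c(120, 0.5, 50), p2 = c(300, 0.10, 60),
                       p3 = c(450, 0.05, 50))
}

#' Generate a full synthetic session with ground truth
#'
#' Renders a three-channel recording (`bifrontal`, `bitemporal`, `arm`) from a
#' [scenario()]: a beat train whose morphology follows the posture segments,
#' breath-hold amplitude-gain responses on the head channels, slow drift
#' shared between head and arm (in phase or inverted per segment), mains
#' contamination, white noise, and seeded blink/talk artifacts. Alongside the
#' recording it returns the generative ground truth — per-beat template
#' amplitudes and compliance class, per-segment drift phase (the REGx truth),
#' breath-hold response peak times, and exact artifact intervals — sufficient
#' to score every downstream stage.
#'
#' @param scn a [scenario()].
#' @return A list with elements `record` (a [signal_record()] with breath-hold
#'   and posture annotations) and `truth` (list: `beats`, `segments`,
#'   `bh_events`, `artifacts`).
#' @export
generate_session <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  fs <- scn$fs
  n <- round(scn$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  rr <- 60 / scn$heart_rate_bpm
  onsets <- seq(0, scn$duration_s - rr, by = rr)
  onset_idx <- round(onsets * fs) + 1
  lens <- diff(c(onset_idx, n + 1))

  seg <- scn$posture_segments
  seg_of <- function(times) {
    findInterval(times, c(seg$start_s, scn$duration_s),
                 rightmost.closed = TRUE, all.inside = TRUE)
  }
  beat_seg <- seg_of(onsets)
  gains <- bh_gain_profile(onsets, scn$bh_events)

  out <- with_seed(scn$seed, {
    chans <- list(bifrontal = numeric(n), bitemporal = numeric(n),
                  arm = numeric(n))
    scale_ch <- c(bifrontal = 1, bitemporal = 0.9, arm = 1)
    resp_phase <- stats::runif(1, 0, 2 * pi)
    resp_of <- function(t) 1 + scn$resp_mod$depth *
      sin(2 * pi * scn$resp_mod$freq_hz * t + resp_phase)
    truth_rows <- vector("list", length(onsets))
    for (k in seq_along(onsets)) {
      bp <- scn$beat_params[[seg$posture[beat_seg[k]]]]
      g <- gains[k]
      i0 <- onset_idx[k]
      idx <- i0:(i0 + lens[k] - 1)
      rr_k <- lens[k] / fs
      resp_k <- resp_of(onsets[k])
      for (ch in c("bifrontal", "bitemporal")) {
        jit <- resp_k * (1 + stats::rnorm(1, 0, scn$beat_jitter_sd))
        chans[[ch]][idx] <- chans[[ch]][idx] +
          scale_ch[ch] * render_beat(bp, rr_k, fs, amp_scale = g * jit,
                                     diastolic_runoff = 0.05)
      }
      jit_a <- resp_k * (1 + stats::rnorm(1, 0, scn$beat_jitter_sd))
      chans$arm[idx] <- chans$arm[idx] +
        render_beat(arm_beat_params(), rr_k, fs, amp_scale = jit_a,
                    diastolic_runoff = 0.05)
      truth_rows[[k]] <- data.frame(
        onset_s = onsets[k], posture = seg$posture[beat_seg[k]],
        bh_gain = g,
        p1_amp = bp$p1[2] * g, p2_amp = bp$p2[2] * g, p3_amp = bp$p3[2] * g,
        p1_latency_ms = bp$p1[1], p2_latency_ms = bp$p2[1],
        p2_p1_ratio = bp$p2[2] / bp$p1[2])
    }
    # slow drift: common to head channels; arm copy negated in INVERTED segments
    d <- scn$drift$amplitude * sin(2 * pi * scn$drift$freq_hz * tt)
    arm_sign <- ifelse(scn$drift$common_phase[seg_of(tt)] == "INVERTED", -1, 1)
    chans$bifrontal <- chans$bifrontal + d
    chans$bitemporal <- chans$bitemporal + d
    chans$arm <- chans$arm + arm_sign * d
    for (ch in names(chans)) {
      chans[[ch]] <- chans[[ch]] + stats::rnorm(n, 0, scn$noise_sd)
    }
    list(chans = chans, beats = do.call(rbind, truth_rows))
  })

  samples <- cbind(bifrontal = out$chans$bifrontal,
                   bitemporal = out$chans$bitemporal,
                   arm = out$chans$arm)
  ann <- annotations_frame(
    seg$start_s, paste0("POSTURE_", seg$posture))
  if (nrow(scn$bh_events)) {
    bh <- scn$bh_events
    ann <- rbind(ann,
                 annotations_frame(bh$start_s, rep("BH_START", nrow(bh))),
                 annotations_frame(bh$start_s + bh$duration_s,
                                   rep("BH_END", nrow(bh))))
  }
  ann <- ann[order(ann$time_s), , drop = FALSE]
  rownames(ann) <- NULL
  rec <- signal_record(samples, fs, annotations = ann)
  rec <- inject_mains(rec, scn$mains$freq_hz, scn$mains$amplitude)

  art <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    kind = character(0))
  if (scn$artifact_rate > 0) {
    inj <- inject_artifacts(rec, rate = scn$artifact_rate,
                            seed = scn$seed + 1L)
    rec <- inj$record
    art <- inj$intervals
  }

  beats <- out$beats
  beats$true_class <- ifelse(beats$p2_p1_ratio < 1, "GOOD_ICC", "POOR_ICC")
  segments <- seg
  segments$drift_phase <- scn$drift$common_phase
  segments$true_regx <- ifelse(segments$drift_phase == "INVERTED", -1, 1)
  bh_truth <- scn$bh_events
  if (nrow(bh_truth)) {
    bh_truth$true_peak_delay_s <- bh_truth$duration_s + bh_truth$peak_after_end_s
    bh_truth$true_bl_percent <- 100 * (bh_truth$amplitude_gain - 1)
  }
  list(record = rec,
       truth = list(beats = beats, segments = segments,
                    bh_events = bh_truth, artifacts = art))
}

#' Add powerline (mains) contamination
#'
#' Adds a fixed-phase sinusoid of the given frequency and amplitude to every
#' channel. Deterministic; an amplitude of zero is the identity.
#'
#' @param record a [signal_record()].
#' @param freq_hz mains frequency (50 or 60 Hz typically); must be below
#'   `fs/2`.
#' @param amplitude peak amplitude in signal units.
#' @return The contaminated [signal_record()].
#' @export
inject_mains <- function(record, freq_hz = 50, amplitude = 0.02) {
  if (freq_hz >= record$fs / 2) {
    stop_regwave("mains frequency must be below fs/2 (", record$fs / 2, " Hz)")
  }
  if (amplitude == 0) return(record)
  n <- nrow(record$samples)
  tt <- (seq_len(n) - 1) / record$fs
  w <- amplitude * sin(2 * pi * freq_hz * tt)
  record$samples <- record$samples + w
  record
}

#' Inject blink/talk artifacts with known intervals
#'
#' Corrupts the recording with a seeded number of events (Poisson with mean
#' `rate * duration / 60`): `BLINK_SPIKE` adds a large brief Gaussian
#' transient (default 5x a unit beat amplitude over ~0.2 s), `TALK_BURST` a
#' 10 Hz oscillation burst of ~1.5 s. The exact corrupted intervals are
#' returned so detector sensitivity is directly measurable.
#'
#' @param record a [signal_record()].
#' @param rate events per minute (>= 0).
#' @param kinds artifact kinds to draw from.
#' @param seed RNG seed for event count, times and kinds.
#' @param blink_amplitude,talk_amplitude peak amplitudes in signal units.
#' @return list with `record` (corrupted copy) and `intervals` (data frame
#'   `start_s`, `end_s`, `kind`), empty when `rate` is zero.
#' @export
inject_artifacts <- function(record, rate,
                             kinds = c("BLINK_SPIKE", "TALK_BURST"),
                             seed = 1L, blink_amplitude = 5,
                             talk_amplitude = 2) {
  if (rate < 0) stop_regwave("artifact rate must be >= 0")
  kinds <- match.arg(kinds, several.ok = TRUE)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      kind = character(0))
  if (rate == 0) return(list(record = record, intervals = empty))
  dur <- duration_s(record)
  fs <- record$fs
  n <- nrow(record$samples)
  with_seed(seed, {
    n_ev <- stats::rpois(1, rate * dur / 60)
    centers <- if (n_ev > 0) sort(stats::runif(n_ev, 1, dur - 2)) else numeric(0)
    kind <- if (n_ev > 0) sample(kinds, n_ev, replace = TRUE) else character(0)
    rows <- vector("list", n_ev)
    tt <- (seq_len(n) - 1) / fs
    for (i in seq_len(n_ev)) {
      if (kind[i] == "BLINK_SPIKE") {
        half <- 0.1
        sel <- which(tt >= centers[i] - half & tt < centers[i] + half)
        bump <- blink_amplitude * exp(-((tt[sel] - centers[i])^2) / (2 * 0.03^2))
        record$samples[sel, ] <- record$samples[sel, ] + bump
      } else {
        half <- 0.75
        sel <- which(tt >= centers[i] - half & tt < centers[i] + half)
        burst <- talk_amplitude * sin(2 * pi * 10 * (tt[sel] - centers[i])) *
          sin(pi * (tt[sel] - (centers[i] - half)) / (2 * half))^2
        record$samples[sel, ] <- record$samples[sel, ] + burst
      }
      rows[[i]] <- data.frame(start_s = max(0, centers[i] - half),
                              end_s = min(dur, centers[i] + half),
                              kind = kind[i])
    }
    list(record = record,
         intervals = if (n_ev > 0) do.call(rbind, rows) else empty)
  })
}
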