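#' Declarative simulation scenario
#'
#' A `scenario` is a complete, seeded description of a synthetic recording
#' session: posture segments with their own beat morphology, breath-hold
#' events with an amplitude-gain response profile, mains contamination,
#' slow respiration-band baseline drift shared (in phase or inverted) between
#' head and arm channels, and an artifact rate. The same scenario with the
#' same seed always renders bit-identical signals.
#'
#' @param duration_s total length in seconds.
#' @param fs sampling rate in Hz (default 200).
#' @param heart_rate_bpm heart rate in beats per minute.
#' @param beat_params named list with one [beat_template_params()] per
#'   posture appearing in `posture_segments` (`SUPINE`, `HDT`).
#' @param posture_segments data frame with columns `start_s`, `end_s`,
#'   `posture`; segments must be non-overlapping, ordered, and cover
#'   `[0, duration_s)`.
#' @param bh_events data frame with columns `start_s`, `duration_s`,
#'   `amplitude_gain`, `response_latency_s` and optionally `peak_after_end_s`
#'   (seconds after breath-hold end at which the gain peaks; default 10).
#'   Events must lie inside the recording. A gain of 1 means no response.
#' @param mains list `(freq_hz, amplitude)`; the default is 50 Hz, the
#'   powerline frequency of the original recordings. Must satisfy
#'   `fs > 2 * freq_hz`.
#' @param drift list `(freq_hz, amplitude, common_phase)` describing a slow
#'   sinusoidal baseline co-fluctuation of head and arm channels.
#'   `common_phase` is either a single value or one per posture segment, each
#'   `"IN_PHASE"` or `"INVERTED"`; inverted segments have the arm drift
#'   negated, which is the ground truth for a REGx of -1.
#' @param artifact_rate artifact events per minute (blink spikes and talk
#'   bursts, drawn from the scenario seed).
#' @param noise_sd additive white-noise standard deviation in signal units.
#' @param resp_mod `list(freq_hz, depth)` respiratory amplitude modulation of
#'   the beat train: beat amplitudes are multiplied by
#'   `1 + depth * sin(2 pi freq_hz t + phase)` with a seeded phase, common to
#'   all channels — the dominant, structured part of beat-to-beat pulse
#'   amplitude variability.
#' @param beat_jitter_sd residual white per-beat multiplicative amplitude
#'   jitter (fractional standard deviation) on top of the respiratory
#'   modulation.
#' @param seed integer RNG seed; with the scenario it fully determines the
#'   rendered bytes.
#' @return An object of class `scenario`.
#' @seealso [generate_session()], [default_session_scenario()]
#' @export
scenario <- function(duration_s,
                     fs = 200,
                     heart_rate_bpm = 70,
                     beat_params = list(SUPINE = beat_template_params()),
                     posture_segments = data.frame(
                       start_s = 0, end_s = duration_s, posture = "SUPINE"),
                     bh_events = NULL,
                     mains = list(freq_hz = 50, amplitude = 0.02),
                     drift = list(freq_hz = 1 / 150, amplitude = 0.05,
                                  common_phase = "IN_PHASE"),
                     artifact_rate = 0,
                     noise_sd = 0.005,
                     resp_mod = list(freq_hz = 0.25, depth = 0.02),
                     beat_jitter_sd = 0.005,
                     seed = 1L) {
  if (duration_s <= 0 || fs <= 0) stop_regwave("duration_s and fs must be positive")
  seg <- as.data.frame(posture_segments)
  seg <- seg[order(seg$start_s), , drop = FALSE]
  rownames(seg) <- NULL
  if (abs(seg$start_s[1]) > 1e-9 ||
      abs(seg$end_s[nrow(seg)] - duration_s) > 1e-9 ||
      (nrow(seg) > 1 && any(abs(seg$end_s[-nrow(seg)] - seg$start_s[-1]) > 1e-9))) {
    stop_regwave("posture segments must tile [0, duration_s) without gaps or overlaps")
  }
  if (any(!seg$posture %in% names(beat_params))) {
    stop_regwave("beat_params must name every posture used in posture_segments")
  }
  for (bp in beat_params) stopifnot(inherits(bp, "beat_template_params"))
  if (!is.null(bh_events)) {
    bh_events <- as.data.frame(bh_events)
    if (is.null(bh_events$peak_after_end_s)) bh_events$peak_after_end_s <- 10
    if (is.null(bh_events$response_latency_s)) bh_events$response_latency_s <- 2
    with_end <- bh_events$start_s + bh_events$duration_s
    if (any(bh_events$start_s < 0) || any(with_end > duration_s)) {
      stop_regwave("breath-hold events must lie inside the recording")
    }
  } else {
    bh_events <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                            amplitude_gain = numeric(0),
                            response_latency_s = numeric(0),
                            peak_after_end_s = numeric(0))
  }
  if (fs <= 2 * mains$freq_hz) {
    stop_regwave("fs must exceed twice the mains frequency")
  }
  phases <- rep_len(drift$common_phase, nrow(seg))
  if (any(!phases %in% c("IN_PHASE", "INVERTED"))) {
    stop_regwave("drift common_phase must be IN_PHASE or INVERTED")
  }
  drift$common_phase <- phases
  if (artifact_rate < 0) stop_regwave("artifact_rate must be >= 0")
  structure(list(duration_s = duration_s, fs = fs,
                 heart_rate_bpm = heart_rate_bpm,
                 beat_params = beat_params, posture_segments = seg,
                 bh_events = bh_events, mains = mains, drift = drift,
                 artifact_rate = artifact_rate, noise_sd = noise_sd,
                 resp_mod = resp_mod, beat_jitter_sd = beat_jitter_sd,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %.0f s @ %g Hz, HR %g bpm, seed %d\n",
              x$duration_s, x$fs, x$heart_rate_bpm, x$seed))
  cat(sprintf("  postures: %s\n",
              paste(sprintf("%s[%g,%g)", x$posture_segments$posture,
                            x$posture_segments$start_s, x$posture_segments$end_s),
                    collapse = " ")))
  cat(sprintf("  breath-holds: %d; mains %g Hz x %g; artifact rate %g/min\n",
              nrow(x$bh_events), x$mains$freq_hz, x$mains$amplitude,
              x$artifact_rate))
  invisible(x)
}

#' Reference full-session scenario
#'
#' The study conditions rendered as a scenario: a supine control period with
#' three 30-second breath-holds separated by rests, followed by a head-down
#' tilt (HDT) period. Supine beats have good-compliance morphology
#' (P2/P1 = 0.8); during HDT the tidal (P2) amplitude is raised by the factor
#' `hdt_p2_gain` (default 1.4, giving P2/P1 = 1.12, a poor-compliance
#' morphology with the catacrotic shoulder tendency the tilt produces).
#' Breath-holds multiply beat amplitudes by `bh_gain`, ramping up from
#' `bh_latency_s` after the hold starts and peaking `bh_peak_after_end_s`
#' seconds after it ends. The slow drift shared by head and arm channels is in
#' phase during control and inverted during HDT, so the ground-truth REGx is
#' +1 in control and -1 in HDT.
#'
#' @param control_s,hdt_s lengths of the control and HDT periods (seconds).
#' @param bh_gain breath-hold amplitude gain (default 1.16, the magnitude of
#'   pulse-amplitude increase breath-holding typically produces).
#' @param bh_latency_s response latency after the hold command (seconds).
#' @param bh_peak_after_end_s gain peak time relative to the hold end.
#' @param hdt_p2_gain multiplier applied to the supine P2 amplitude during HDT.
#' @param artifact_rate artifact events per minute.
#' @param seed RNG seed.
#' @return A [scenario()].
#' @export
default_session_scenario <- function(control_s = 900, hdt_s = 900,
                                     bh_gain = 1.16, bh_latency_s = 2,
                                     bh_peak_after_end_s = 10,
                                     hdt_p2_gain = 1.4,
                                     artifact_rate = 1, seed = 1L) {
  supine <- beat_template_params(p1 = c(100, 1.0, 30), p2 = c(250, 0.8, 40),
                                 p3 = c(400, 0.3, 40))
  hdt <- beat_template_params(p1 = c(100, 1.0, 30),
                              p2 = c(250, 0.8 * hdt_p2_gain, 40),
                              p3 = c(400, 0.3, 40))
  dur <- control_s + hdt_s
  bh_starts <- c(120, 300, 480)
  bh_starts <- bh_starts[bh_starts + 30 + 90 < control_s]
  bh <- if (length(bh_starts)) {
    data.frame(start_s = bh_starts, duration_s = 30,
               amplitude_gain = bh_gain,
               response_latency_s = bh_latency_s,
               peak_after_end_s = bh_peak_after_end_s)
  }
  scenario(
    duration_s = dur, fs = 200, heart_rate_bpm = 70,
    beat_params = list(SUPINE = supine, HDT = hdt),
    posture_segments = data.frame(
      start_s = c(0, control_s), end_s = c(control_s, dur),
      posture = c("SUPINE", "HDT")),
    bh_events = bh,
    drift = list(freq_hz = 1 / 150, amplitude = 0.05,
                 common_phase = c("IN_PHASE", "INVERTED")),
    artifact_rate = artifact_rate, seed = seed)
}

#' Read a scenario from a YAML file
#'
#' The plain-text scenario format mirrors the [scenario()] arguments. Two
#' `kind`s are supported: `session` (full physiological session) and
#' `sine_pair` (the in-vitro sine demonstration; fields `freq_hz`,
#' `amplitude`, `duration_s`, `fs`, `inversion_intervals` as a list of
#' two-element `[start_s, end_s]` lists, optional `drift`).
#'
#' @param path YAML file path.
#' @return A [scenario()] for `kind: session`, or a list of class
#'   `sine_pair_scenario` for `kind: sine_pair`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_regwave("scenario file not found: ", path)
  y <- yaml::read_yaml(path)
  kind <- y$kind %||% "session"
  if (kind == "sine_pair") {
    return(structure(list(
      freq_hz = y$freq_hz %||% 10, amplitude = y$amplitude %||% 1,
      fs = y$fs %||% 200, duration_s = y$duration_s %||% 1500,
      inversion_intervals = lapply(y$inversion_intervals %||% list(),
                                   function(iv) as.numeric(unlist(iv))),
      drift = y$drift), class = "sine_pair_scenario"))
  }
  if (kind != "session") stop_regwave("unknown scenario kind: ", kind)
  bp <- lapply(y$beat_params, function(p) {
    beat_template_params(p1 = as.numeric(unlist(p$p1)),
                         p2 = as.numeric(unlist(p$p2)),
                         p3 = as.numeric(unlist(p$p3)),
                         baseline = p$baseline %||% 0)
  })
  seg <- do.call(rbind, lapply(y$posture_segments, as.data.frame))
  bh <- if (length(y$bh_events)) do.call(rbind, lapply(y$bh_events, as.data.frame))
  args <- list(duration_s = y$duration_s, beat_params = bp,
               posture_segments = seg, bh_events = bh)
  for (nm in c("fs", "heart_rate_bpm", "mains", "drift", "artifact_rate",
               "noise_sd", "resp_mod", "beat_jitter_sd", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(scenario, args)
}
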