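#' Beat template parameters for the synthetic pulse-wave generator
#'
#' A synthetic REG/bioimpedance beat is the sum of three bell-shaped (Gaussian)
#' sub-waves realising the classic intracranial pulse taxonomy: P1 (percussion
#' wave, arterial inflow), P2 (tidal wave, intracranial compliance) and P3
#' (dicrotic wave, venous/valve). Each sub-wave is given as
#' `c(latency_ms, amplitude, width_ms)` where `width_ms` is the Gaussian
#' standard deviation. Latencies must be strictly increasing (P1 < P2 < P3),
#' widths positive and amplitudes non-negative; overlapping widths that fuse
#' the peaks into a single triangular hump are deliberately allowed — that is
#' how the poor-compliance "triangular" morphology class is generated.
#'
#' @param p1,p2,p3 numeric triplets `c(latency_ms, amplitude, width_ms)`.
#' @param baseline baseline level in signal units.
#' @return An object of class `beat_template_params`.
#' @examples
#' beat_template_params() # good-compliance default (P1 > P2)
#' @export
beat_template_params <- function(p1 = c(100, 1.0, 30),
                                 p2 = c(250, 0.6, 40),
                                 p3 = c(400, 0.3, 40),
                                 baseline = 0) {
  pk <- function(v, nm) {
    if (length(v) != 3) stop_regwave(nm, " must be c(latency_ms, amplitude, width_ms)")
    if (v[3] <= 0) stop_regwave(nm, " width must be > 0")
    if (v[2] < 0) stop_regwave(nm, " amplitude must be >= 0")
    stats::setNames(as.numeric(v), c("latency_ms", "amplitude", "width_ms"))
  }
  p1 <- pk(p1, "p1"); p2 <- pk(p2, "p2"); p3 <- pk(p3, "p3")
  if (!(p1[1] < p2[1] && p2[1] < p3[1])) {
    stop_regwave("sub-wave latencies must be strictly increasing (p1 < p2 < p3)")
  }
  structure(list(p1 = p1, p2 = p2, p3 = p3, baseline = as.numeric(baseline)),
            class = "beat_template_params")
}

#' @export
print.beat_template_params <- function(x, ...) {
  cat("<beat_template_params>\n")
  for (nm in c("p1", "p2", "p3")) {
    cat(sprintf("  %s: %g ms, amp %g, width %g ms\n",
                nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  }
  cat(sprintf("  baseline: %g\n", x$baseline))
  invisible(x)
}

#' Render one synthetic beat
#'
#' Evaluates the three-Gaussian beat template over one RR interval. A linear
#' endpoint correction pins the first and last sample exactly to the baseline
#' so that concatenated beats join without steps.
#'
#' @param params a [beat_template_params()].
#' @param rr_s RR interval (beat duration) in seconds; must exceed the P3
#'   latency plus three P3 widths so the beat decays before the next onset.
#' @param fs sampling rate in Hz.
#' @param amp_scale optional scalar multiplying all three sub-wave amplitudes
#'   (used for breath-hold gain modulation).
#' @param diastolic_runoff height (signal units) of a linear diastolic decay
#'   from beat onset to zero at beat end. The default 0 keeps the template
#'   pure (both endpoints exactly at baseline); the session generator uses a
#'   small positive value so concatenated beats descend into each onset the
#'   way a real pulse wave does, making every onset a sharp minimum.
#' @return numeric vector of `round(rr_s * fs)` samples.
#' @examples
#' w <- render_beat(beat_template_params(), rr_s = 1, fs = 200)
#' which.max(w) / 200   # ~ 0.1 s, the P1 latency
#' @export
render_beat <- function(params, rr_s, fs, amp_scale = 1,
                        diastolic_runoff = 0) {
  stopifnot(inherits(params, "beat_template_params"))
  min_rr <- (params$p3[1] + 3 * params$p3[3]) / 1000
  if (rr_s <= min_rr) {
    stop_regwave("rr_s (", rr_s, " s) must exceed p3 latency + 3 widths (",
                 min_rr, " s)")
  }
  n <- round(rr_s * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  y <- rep(0, n)
  for (nm in c("p1", "p2", "p3")) {
    pk <- params[[nm]]
    y <- y + amp_scale * pk[2] * exp(-((t_ms - pk[1])^2) / (2 * pk[3]^2))
  }
  # pin endpoints to baseline with a linear correction (tails are tiny but
  # nonzero; exact endpoint continuity keeps the beat train step-free)
  y <- y - (y[1] + (y[n] - y[1]) * (seq_len(n) - 1) / (n - 1))
  if (diastolic_runoff > 0) {
    y <- y + diastolic_runoff * (1 - (seq_len(n) - 1) / (n - 1))
  }
  params$baseline + y
}
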