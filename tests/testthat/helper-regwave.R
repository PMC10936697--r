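# Shared fixtures and independent oracles for the test suite.

# Hand-built epoch series on the standard 10-s grid.
make_epoch_series <- function(values, epoch_s = 10, valid = NULL) {
  structure(list(epoch_s = epoch_s,
                 times = (seq_along(values) - 0.5) * epoch_s,
                 values = as.numeric(values),
                 valid = valid %||% rep(TRUE, length(values))),
            class = "epoch_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent Pearson oracle: textbook sum formula, no call to stats::cor.
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Standard good-compliance beat template used across morphology tests.
std_beat <- function(p2_amp = 0.6) {
  beat_template_params(p1 = c(100, 1.0, 30), p2 = c(250, p2_amp, 40),
                       p3 = c(400, 0.3, 40))
}

# A clean noisy beat train as a record: n_beats beats of rr_s seconds.
beat_train_record <- function(params, n_beats, rr_s = 1, fs = 200,
                              noise_sd = 0, runoff = 0.05, seed = 1) {
  w <- render_beat(params, rr_s, fs, diastolic_runoff = runoff)
  x <- rep(w, n_beats)
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + rnorm(length(x), 0, noise_sd)
  }
  signal_record(x, fs = fs)
}

# One small full session reused by several files (cached per test run).
small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scn <- default_session_scenario(control_s = 420, hdt_s = 420,
                                      artifact_rate = 1, seed = 11)
      cache <<- generate_session(scn)
    }
    cache
  }
})
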