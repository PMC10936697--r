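test_that("rendered beats place their sub-wave maxima at the configured latencies", {
  fs <- 200
  w <- render_beat(std_beat(), rr_s = 1, fs = fs)
  expect_length(w, 200)
  # well-separated sub-waves: each local maximum within 1 sample of its latency
  maxima <- which(diff(sign(diff(w))) == -2) + 1
  expect_length(maxima, 3)
  # within one sample (5 ms) of the configured latencies
  expect_true(all(abs((maxima - 1) / fs * 1000 - c(100, 250, 400)) <= 5))
  # endpoints pinned to baseline
  expect_equal(w[1], 0)
  expect_equal(w[length(w)], 0)
})

test_that("beat rendering handles degenerate and inverted-amplitude templates", {
  flat <- render_beat(beat_template_params(p1 = c(100, 0, 30),
                                           p2 = c(250, 0, 40),
                                           p3 = c(400, 0, 40)), 1, 200)
  expect_true(all(flat == 0))
  dominant_p2 <- render_beat(beat_template_params(p1 = c(100, 1.0, 30),
                                                  p2 = c(250, 1.2, 40),
                                                  p3 = c(400, 0.3, 40)), 1, 200)
  expect_equal((which.max(dominant_p2) - 1) / 200 * 1000, 250, tolerance = 0.06)
  expect_error(render_beat(std_beat(), rr_s = 0.4, fs = 200), "rr_s")
  expect_error(beat_template_params(p1 = c(300, 1, 30), p2 = c(250, 1, 30),
                                    p3 = c(400, 1, 30)), "increasing")
})

test_that("sine pair construction matches the in-vitro demonstration layout", {
  rec <- generate_sine_pair(10, 1, 200, 60, drift = NULL)
  expect_equal(nrow(rec$samples), 12000)
  expect_identical(get_channel(rec, "head"), get_channel(rec, "arm"))

  rec2 <- generate_sine_pair(10, 1, 200, 60, list(c(20, 40)))
  h <- get_channel(rec2, "head"); a <- get_channel(rec2, "arm")
  tt <- (seq_along(h) - 1) / 200
  inside <- tt >= 20 & tt < 40
  expect_identical(h[inside], -a[inside])
  expect_identical(h[!inside], a[!inside])
})

test_that("an inversion starting at 988.35 s begins at sample index 197670", {
  rec <- generate_sine_pair(10, 1, 200, 1200, list(c(988.35, 1100)))
  h <- get_channel(rec, "head"); a <- get_channel(rec, "arm")
  first_inverted <- which(h != a)[1]
  expect_identical(first_inverted - 1L, 197670L)  # 0-based sample index
})

test_that("inversion intervals outside the recording are rejected", {
  expect_error(generate_sine_pair(10, 1, 200, 60, list(c(50, 70))), "outside")
  expect_error(generate_sine_pair(120, 1, 200, 10), "fs/2")
})

test_that("session generation is bit-deterministic in scenario + seed", {
  scn <- default_session_scenario(control_s = 120, hdt_s = 120,
                                  artifact_rate = 2, seed = 3)
  a <- generate_session(scn)
  b <- generate_session(scn)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth$beats, b$truth$beats)
  scn2 <- default_session_scenario(control_s = 120, hdt_s = 120,
                                   artifact_rate = 2, seed = 4)
  expect_false(identical(generate_session(scn2)$record$samples,
                         a$record$samples))
})

test_that("session annotations mark every breath-hold and posture change, inside the record", {
  ses <- small_session()
  ann <- ses$record$annotations
  expect_equal(sum(ann$label == "BH_START"), nrow(ses$truth$bh_events))
  expect_equal(sum(ann$label == "BH_END"), nrow(ses$truth$bh_events))
  expect_equal(sum(grepl("^POSTURE_", ann$label)), 2)
  expect_true(all(ann$time_s >= 0 & ann$time_s <= duration_s(ses$record)))
})

test_that("without artifacts and mains the rendered signal is the beat train plus drift and noise floor", {
  scn <- scenario(duration_s = 30, beat_params = list(SUPINE = std_beat()),
                  mains = list(freq_hz = 50, amplitude = 0),
                  artifact_rate = 0, noise_sd = 0, seed = 2)
  ses <- generate_session(scn)
  x <- get_channel(ses$record, "bifrontal")
  tt <- (seq_along(x) - 1) / 200
  drift <- 0.05 * sin(2 * pi * tt / 150)
  resid <- x - drift
  # pure beat train: every value within the template's amplitude envelope
  expect_true(all(resid > -0.01))
  expect_lt(max(resid), 1.2)
  expect_equal(nrow(ses$truth$artifacts), 0)
})

test_that("mains injection is additive, deterministic and validated", {
  rec <- signal_record(matrix(0, nrow = 2000, ncol = 2), fs = 200)
  expect_identical(inject_mains(rec, 50, 0)$samples, rec$samples)
  out <- inject_mains(rec, 50, 0.5)
  tt <- (seq_len(2000) - 1) / 200
  expect_equal(out$samples[, 1], 0.5 * sin(2 * pi * 50 * tt))
  expect_error(inject_mains(rec, 120, 0.1), "fs/2")
})

test_that("artifact injection returns the exact corrupted intervals, reproducibly", {
  rec <- signal_record(matrix(0, nrow = 600 * 200, ncol = 1), fs = 200)
  none <- inject_artifacts(rec, rate = 0)
  expect_identical(none$record$samples, rec$samples)
  expect_equal(nrow(none$intervals), 0)

  a <- inject_artifacts(rec, rate = 5, seed = 17)
  b <- inject_artifacts(rec, rate = 5, seed = 17)
  expect_identical(a$intervals, b$intervals)
  expect_identical(a$record$samples, b$record$samples)
  set.seed(17)
  expect_equal(nrow(a$intervals), rpois(1, 5 * 600 / 60))
  expect_true(all(a$intervals$end_s <= duration_s(rec)))
  expect_error(inject_artifacts(rec, rate = -1), ">= 0")
})

test_that("scenario validation rejects malformed protocols", {
  expect_error(scenario(100, posture_segments = data.frame(
    start_s = c(0, 40), end_s = c(50, 100), posture = c("SUPINE", "SUPINE"))),
    "tile")
  expect_error(scenario(100, bh_events = data.frame(
    start_s = 90, duration_s = 30, amplitude_gain = 1.2)), "inside")
  expect_error(scenario(100, mains = list(freq_hz = 120, amplitude = 0.1)),
               "twice")
  expect_error(scenario(100, drift = list(freq_hz = 0.01, amplitude = 0.05,
                                          common_phase = "SIDEWAYS")),
               "IN_PHASE")
})
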