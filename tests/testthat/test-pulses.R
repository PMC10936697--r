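test_that("beat segmentation counts and spaces onsets by the heart rate", {
  rec60 <- beat_train_record(std_beat(), n_beats = 30, rr_s = 1)
  b60 <- segment_beats(rec60, 1)
  expect_true(nrow(b60) %in% 29:30)

  rec75 <- beat_train_record(std_beat(), n_beats = 38, rr_s = 0.8)
  b75 <- segment_beats(rec75, 1)
  expect_true(all(abs(diff(b75$onset_index) - 160) <= 1))

  flat <- signal_record(matrix(0, nrow = 6000, ncol = 1), fs = 200)
  expect_equal(nrow(segment_beats(flat, 1)), 0)
})

test_that("beats overlapping a mask are dropped", {
  rec <- beat_train_record(std_beat(), n_beats = 30, rr_s = 1)
  m <- artifact_mask(data.frame(start_s = 10, end_s = 15, reason = "x"))
  all_b <- segment_beats(rec, 1)
  kept <- segment_beats(rec, 1, mask = m)
  expect_lt(nrow(kept), nrow(all_b))
  expect_false(any(kept$onset_s < 15 & kept$end_s > 10))
})

test_that("feature extraction recovers the generative morphology", {
  rec <- beat_train_record(std_beat(), n_beats = 10, rr_s = 1, runoff = 0)
  beats <- data.frame(onset_index = seq(1, by = 200, length.out = 9),
                      end_index = seq(201, by = 200, length.out = 9))
  f <- extract_features(rec, beats[4, ], channel = 1)
  expect_equal(f$p1_amp, 1.0, tolerance = 0.02)
  expect_equal(f$p2_amp, 0.6, tolerance = 0.05)
  expect_equal(f$anacrotic_ms, 100, tolerance = 0.06)
  expect_equal(f$p2_time_ms, 250, tolerance = 0.05)
  expect_equal(f$morph_class, "GOOD_ICC")
  expect_false(f$shoulder)
})

test_that("a dominant tidal wave gives ratio > 1 and the poor-compliance class", {
  rec <- beat_train_record(std_beat(p2_amp = 1.2), n_beats = 6, rr_s = 1,
                           runoff = 0)
  f <- extract_features(rec, list(onset_index = 401, end_index = 600),
                        channel = 1)
  expect_gt(f$p2_p1_ratio, 1)
  expect_equal(f$morph_class, "POOR_ICC")
})

test_that("fused beats take the triangular path and never crash", {
  fused <- beat_template_params(p1 = c(150, 1, 80), p2 = c(250, 0.9, 80),
                                p3 = c(350, 0.5, 80))
  w <- render_beat(fused, 1, 200)
  f <- extract_features(signal_record(w, fs = 200),
                        list(onset_index = 1, end_index = 200), channel = 1)
  expect_true(f$fused)
  expect_equal(f$morph_class, "TRIANGULAR")

  # beat with no local maximum at all: flagged, not an error
  ramp <- signal_record(matrix(seq(0, 1, length.out = 200), ncol = 1), fs = 200)
  f2 <- extract_features(ramp, list(onset_index = 1, end_index = 200),
                         channel = 1)
  expect_true(is.na(f2$p1_amp))
  expect_true(is.na(f2$morph_class))
})

test_that("the catacrotic shoulder is found only when no true second peak exists", {
  fs <- 200
  two_peak <- render_beat(std_beat(), 1, fs)
  m <- which(diff(sign(diff(two_peak))) == -2) + 1
  expect_false(detect_shoulder(two_peak, m[1], fs)$shoulder)

  mono <- render_beat(beat_template_params(p1 = c(100, 1, 40),
                                           p2 = c(250, 0, 60),
                                           p3 = c(400, 0, 60)), 1, fs)
  expect_false(detect_shoulder(mono, which.max(mono), fs)$shoulder)

  # sub-threshold P2 bump on the descending limb
  sub <- render_beat(beat_template_params(p1 = c(100, 1.0, 30),
                                          p2 = c(190, 0.45, 40),
                                          p3 = c(400, 0.1, 40)), 1, fs)
  sh <- detect_shoulder(sub, which.max(sub), fs)
  expect_true(sh$shoulder)
  expect_equal(sh$location_ms, 190, tolerance = 0.1)
})

test_that("shoulder-derived P2 keeps tidal statistics computable", {
  sub <- beat_template_params(p1 = c(100, 1.0, 30), p2 = c(190, 0.45, 40),
                              p3 = c(400, 0.1, 40))
  rec <- beat_train_record(sub, n_beats = 6, rr_s = 1, runoff = 0)
  f <- extract_features(rec, list(onset_index = 201, end_index = 400),
                        channel = 1)
  expect_true(f$shoulder)
  expect_false(is.na(f$p2_amp))
  expect_equal(f$morph_class, "GOOD_ICC")
})

test_that("morphology classification follows the P1/P2 dominance rules", {
  expect_equal(classify_morphology(list(p1_amp = 1.0, p2_amp = 0.6,
                                        fused = FALSE)), "GOOD_ICC")
  expect_equal(classify_morphology(list(p1_amp = 1.0, p2_amp = 1.2,
                                        fused = FALSE)), "POOR_ICC")
  # tie breaks toward pathology
  expect_equal(classify_morphology(list(p1_amp = 1.0, p2_amp = 1.0,
                                        fused = FALSE)), "POOR_ICC")
  expect_equal(classify_morphology(list(p1_amp = 1.0, p2_amp = NA,
                                        fused = TRUE)), "TRIANGULAR")
  expect_true(is.na(classify_morphology(list(p1_amp = NA, p2_amp = 1,
                                             fused = FALSE))))
})

test_that("anacrotic time is classified against the 180 ms threshold", {
  expect_equal(classify_anacrotic(87), "NORMAL")
  expect_equal(classify_anacrotic(180), "PROLONGED")  # boundary is prolonged
  expect_equal(classify_anacrotic(250), "PROLONGED")
  expect_equal(classify_anacrotic(c(100, 200)), c("NORMAL", "PROLONGED"))
  expect_error(classify_anacrotic(-5), ">= 0")
})

test_that("baseline percent reproduces the worked example and simple identities", {
  expect_equal(round(baseline_percent(1.042, 1.208), 2), 15.93)
  expect_equal(baseline_percent(0.73, 0.73), 0)
  expect_equal(baseline_percent(2.0, 1.0), -50)
  expect_error(baseline_percent(0, 1), "non-zero")
})

test_that("epoch summaries average only over beats whose peak was found", {
  f <- extract_all_features(beat_train_record(std_beat(), 12, 1), 1)
  f <- f[2:11, ]
  s <- summarize_epoch(f)
  expect_equal(s$n_beats, 10)
  expect_equal(s$mean_p1, f$p1_amp[1], tolerance = 1e-6)

  f2 <- f
  f2$p2_amp[1:4] <- NA
  s2 <- summarize_epoch(f2)
  expect_equal(s2$n_p2, 6)
  expect_equal(s2$mean_p2, mean(f$p2_amp[5:10]))
  expect_error(summarize_epoch(f[0, ]), "no beat")
})

test_that("recovered P2/P1 ratio tracks the generative ratio and is monotone", {
  gen <- seq(0.4, 1.3, by = 0.15)
  recovered <- vapply(gen, function(a2) {
    rec <- beat_train_record(std_beat(p2_amp = a2), n_beats = 60, rr_s = 1,
                             noise_sd = 0.005, seed = 5)
    f <- extract_all_features(smooth_running_average(rec), 1)
    mean(f$p2_p1_ratio, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(recovered) > 0))

  # template-level recovery with known beat boundaries: within 5%
  direct <- vapply(gen, function(a2) {
    rec <- beat_train_record(std_beat(p2_amp = a2), n_beats = 60, rr_s = 1,
                             runoff = 0)
    beats <- data.frame(onset_index = seq(1, by = 200, length.out = 59),
                        end_index = seq(201, by = 200, length.out = 59))
    f <- do.call(rbind, lapply(1:59, function(k) {
      extract_features(rec, beats[k, ], channel = 1)
    }))
    mean(f$p2_p1_ratio)
  }, numeric(1))
  expect_true(all(abs(direct / gen - 1) < 0.05))
})

test_that("per-beat invariants hold on a full synthetic session", {
  ses <- small_session()
  sm <- smooth_running_average(ses$record)
  mask <- detect_artifacts(sm)
  f <- extract_all_features(sm, "bifrontal", mask = mask)
  ok <- !is.na(f$p1_amp)
  expect_gt(sum(ok), 500)
  expect_true(all(f$anacrotic_ms[ok] < f$duration_ms[ok]))
  expect_true(all(f$p1_amp[ok] >= 0))
  with_p2 <- ok & !is.na(f$p2_amp)
  expect_true(all(f$p2_time_ms[with_p2] > f$p1_time_ms[with_p2]))
  # classes partition every classifiable beat
  expect_true(all(f$morph_class[ok] %in%
                    c("GOOD_ICC", "POOR_ICC", "TRIANGULAR")))
})
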