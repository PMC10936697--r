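# Build a pulse_features timeline directly from a known amplitude law,
# bypassing signal rendering: one beat per rr_s, P1 = gain(t) * base.
synthetic_timeline <- function(gain_fun, t_end = 240, rr_s = 1, base = 1,
                               p2 = 0.8, seed = NULL) {
  t <- seq(0, t_end, by = rr_s)
  amp <- gain_fun(t) * base
  if (!is.null(seed)) {
    set.seed(seed)
    amp <- amp * (1 + rnorm(length(t), 0, 0.005))
  }
  data.frame(onset_s = t, duration_ms = rr_s * 1000,
             p1_amp = amp, p2_amp = p2 * amp,
             p1_time_ms = 100, p2_time_ms = 250,
             anacrotic_ms = 100, shoulder = FALSE, fused = FALSE,
             morph_class = ifelse(p2 < 1, "GOOD_ICC", "POOR_ICC"),
             p2_p1_ratio = p2)
}

test_that("breath-hold analysis recovers the response timing and size", {
  # gain ramps from 62 s to a peak of 1.2 at 72 s, then recovers
  gain <- function(t) {
    ifelse(t < 62, 1,
           ifelse(t < 72, 1 + 0.2 * (t - 62) / 10,
                  pmax(1, 1.2 - 0.2 * (t - 72) / 30)))
  }
  f <- synthetic_timeline(gain, seed = 1)
  bh <- analyze_breath_hold(f, list(start_s = 60, duration_s = 30))
  expect_equal(bh$peak_delay_s, 12, tolerance = 0.2)
  expect_equal(bh$bl_percent, 20, tolerance = 0.15)
  expect_equal(bh$baseline_p1_mean, 1, tolerance = 0.01)
  # BL% identity with the baseline_percent operation
  expect_equal(bh$bl_percent,
               baseline_percent(bh$baseline_p1_mean, bh$max_p1))
})

test_that("a null breath-hold response reads as ~0 BL%", {
  f <- synthetic_timeline(function(t) rep(1, length(t)), seed = 2)
  bh <- analyze_breath_hold(f, list(start_s = 60, duration_s = 30))
  expect_lt(abs(bh$bl_percent), 1)
})

test_that("breath-hold analysis rejects events without clean baseline or beats", {
  f <- synthetic_timeline(function(t) rep(1, length(t)))
  expect_error(analyze_breath_hold(f, list(start_s = 500, duration_s = 30)),
               "outside")
  f2 <- f[f$onset_s >= 60, ]
  expect_error(
    analyze_breath_hold(f2, list(start_s = 60, duration_s = 30),
                        baseline_window_s = 1),
    "baseline")
})

test_that("the paired t wrapper matches the hand formula and handles degeneracy", {
  same <- paired_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  pt <- paired_test(c(2, 4, 6), c(1, 2, 3))  # differences 1, 2, 3
  expect_equal(pt$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(pt$n, 3)
  # cross-check against the closed-form two-sided p for t = 3.464, df = 2
  expect_equal(pt$p_value, 2 * pt(-sqrt(12), df = 2), tolerance = 1e-12)

  degen <- paired_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(degen$unbounded)
  expect_equal(degen$p_value, 0)
  expect_true(is.infinite(degen$statistic))

  expect_error(paired_test(1, 1), "at least 2")
  expect_error(paired_test(1:3, 1:2), "equal length")
})

test_that("control-vs-HDT comparison recovers the tidal-wave elevation", {
  ctrl <- synthetic_timeline(function(t) rep(1, length(t)), t_end = 300,
                             p2 = 0.8, seed = 3)
  hdt <- synthetic_timeline(function(t) rep(1, length(t)), t_end = 300,
                            p2 = 1.12, seed = 4)
  h <- compare_hdt(ctrl, hdt)
  expect_equal(h$p2_bl_percent, 40, tolerance = 0.02)
  expect_lt(abs(h$p1_bl_percent), 1)
  expect_true(h$p2_elevated)
  expect_lt(h$p2_test$p_value, 0.001)

  null <- compare_hdt(ctrl, ctrl)
  expect_equal(null$p2_bl_percent, 0)
  expect_equal(null$p2_test$p_value, 1)

  expect_error(compare_hdt(ctrl[1:3, ], hdt), ">= 5")
})

test_that("session reports populate every cell and mark missing derivations", {
  ctrl <- synthetic_timeline(function(t) rep(1, length(t)), t_end = 300,
                             p2 = 0.8, seed = 5)
  hdt <- synthetic_timeline(function(t) rep(1, length(t)), t_end = 300,
                            p2 = 1.2, seed = 6)
  h <- compare_hdt(ctrl, hdt)
  bh <- analyze_breath_hold(
    synthetic_timeline(function(t) ifelse(t > 62 & t < 100, 1.15, 1), seed = 7),
    list(start_s = 60, duration_s = 30))

  rep1 <- build_report(list(bifrontal = h, bitemporal = h),
                       bh_results = list(bh), regx_r2 = 1)
  expect_equal(nrow(rep1$table), 2)
  expect_true(all(!is.na(rep1$table$p2_bl_percent)))
  expect_equal(rep1$table$regx_r2, c(1, 1))
  expect_equal(nrow(rep1$breath_holds), 1)

  rep2 <- build_report(list(bifrontal = h), regx_r2 = NA_real_)
  expect_true(is.na(rep2$table$regx_r2))
  expect_equal(nrow(rep2$breath_holds), 0)
})

test_that("the full pipeline recovers session ground truth end to end", {
  ses <- small_session()
  res <- analyze_session(ses$record)
  tr <- ses$truth

  # morphology: supine good compliance, HDT poor compliance
  hdt_start <- tr$segments$start_s[tr$segments$posture == "HDT"]
  for (ch in c("bifrontal", "bitemporal")) {
    f <- res$features[[ch]]
    sup <- f[f$onset_s < hdt_start - 30 & !is.na(f$morph_class), ]
    hdt <- f[f$onset_s >= hdt_start & !is.na(f$morph_class), ]
    expect_gt(mean(sup$morph_class == "GOOD_ICC"), 0.9)
    expect_gt(mean(hdt$morph_class == "POOR_ICC"), 0.9)
  }

  # HDT P2 elevation ~ +40 BL%
  expect_equal(res$hdt$bifrontal$p2_bl_percent, 40, tolerance = 0.15)
  expect_true(res$hdt$bifrontal$p2_elevated)

  # breath-hold response: one event, known gain and peak time
  bh <- res$bh$bifrontal[[1]]
  expect_equal(bh$peak_delay_s, tr$bh_events$true_peak_delay_s[1],
               tolerance = 0.1)
  expect_equal(bh$bl_percent, tr$bh_events$true_bl_percent[1],
               tolerance = 0.12)

  # autoregulation index: passive (in-phase) control, active (inverted) HDT
  rx <- res$regx$bifrontal
  ctrl_w <- rx$valid & rx$times <= hdt_start - 60
  hdt_w <- rx$valid & rx$times > hdt_start + 360
  expect_gt(min(rx$values[ctrl_w]), 0.8)
  expect_lt(max(rx$values[hdt_w]), -0.8)
  expect_gt(res$regx_r2, 0.8)
  expect_equal(nrow(res$report$table), 2)
})
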