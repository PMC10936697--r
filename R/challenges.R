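#' Quantify the response to one breath-hold
#'
#' Baseline P1 is the mean over the clean beats of the `baseline_window_s`
#' seconds preceding the hold command. The response maximum is read the way
#' pulse amplitudes are read in practice — over short periods rather than
#' single beats: each beat's P1 is replaced by the mean over the beats of
#' the surrounding `period_s`-second window, and the maximum of this period
#' amplitude is searched from the command to `search_end_s` seconds after it,
#' wide enough to capture maxima occurring during the hold, shortly after its
#' end, or up to a minute later, all of which occur physiologically. Period
#' averaging matters: single-beat maxima are biased upward by beat-to-beat
#' amplitude variability, inflating both the response size and its timing
#' error. The peak delay is measured from the command to the beat carrying
#' the period maximum, and the amplitude change is expressed as percent of
#' baseline ([baseline_percent()]).
#'
#' @param features data frame of `pulse_features` rows for one channel
#'   (masked beats already excluded), e.g. from [extract_all_features()].
#' @param bh_event list or one-row data frame with `start_s` and
#'   `duration_s`.
#' @param baseline_window_s seconds before the command used for baseline.
#' @param search_end_s end of the maximum search, seconds after the command.
#' @param period_s length of the amplitude-reading period (5–10 s in
#'   practice; default 5).
#' @return An object of class `bh_result`: list with `bh_start_s`,
#'   `bh_end_s`, `baseline_p1_mean`, `max_p1` (peak period-mean P1),
#'   `peak_delay_s`, `bl_percent`, `n_baseline_beats`.
#' @export
analyze_breath_hold <- function(features, bh_event, baseline_window_s = 30,
                                search_end_s = 90, period_s = 5) {
  s <- bh_event$start_s[1]
  d <- bh_event$duration_s[1]
  if (!nrow(features) || s > max(features$onset_s)) {
    stop_regwave("breath-hold event lies outside the feature timeline")
  }
  base <- features[features$onset_s >= s - baseline_window_s &
                     features$onset_s < s & !is.na(features$p1_amp), ]
  if (!nrow(base)) {
    stop_regwave("no clean baseline beat in the ", baseline_window_s,
                 " s before the breath-hold at ", s, " s")
  }
  resp <- features[features$onset_s >= s - period_s &
                     features$onset_s <= s + search_end_s + period_s &
                     !is.na(features$p1_amp), ]
  in_search <- resp$onset_s >= s & resp$onset_s <= s + search_end_s
  if (!any(in_search)) stop_regwave("no clean beat in the response window")
  period_mean <- vapply(resp$onset_s, function(t) {
    mean(resp$p1_amp[resp$onset_s >= t - period_s / 2 &
                       resp$onset_s < t + period_s / 2])
  }, numeric(1))
  baseline <- mean(base$p1_amp)
  cand <- which(in_search)
  imax <- cand[which.max(period_mean[cand])]
  structure(list(bh_start_s = s, bh_end_s = s + d,
                 baseline_p1_mean = baseline,
                 max_p1 = period_mean[imax],
                 peak_delay_s = resp$onset_s[imax] - s,
                 bl_percent = baseline_percent(baseline, period_mean[imax]),
                 n_baseline_beats = nrow(base)),
            class = "bh_result")
}

#' @export
print.bh_result <- function(x, ...) {
  cat(sprintf(
    "<bh_result> hold %.0f-%.0f s: baseline P1 %.3f, max P1 %.3f (+%.2f BL%%), peak delay %.1f s\n",
    x$bh_start_s, x$bh_end_s, x$baseline_p1_mean, x$max_p1, x$bl_percent,
    x$peak_delay_s))
  invisible(x)
}

#' Paired t test wrapper
#'
#' Classical paired t statistic with a documented convention for degenerate
#' input: identical vectors give `t = 0, p = 1`; non-zero differences with
#' zero variance give an unbounded statistic (`Inf`, flagged) with `p = 0`.
#'
#' @param a,b paired numeric vectors of equal length `n >= 2`.
#' @return list: `statistic`, `p_value`, `n`, `unbounded` (logical flag).
#' @export
paired_test <- function(a, b) {
  n <- length(a)
  if (length(b) != n) stop_regwave("paired vectors must have equal length")
  if (n < 2) stop_regwave("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(statistic = 0, p_value = 1, n = n, unbounded = FALSE))
    }
    return(list(statistic = sign(mean(d)) * Inf, p_value = 0, n = n,
                unbounded = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value, n = n,
       unbounded = FALSE)
}

# Per-epoch means of a peak amplitude, used as the unit of the paired test
# (per-beat values are serially correlated; epoch means are closer to
# exchangeable).
epoch_means_of <- function(features, column, epoch_s = 10) {
  f <- features[!is.na(features[[column]]), ]
  if (!nrow(f)) return(numeric(0))
  ep <- floor((f$onset_s - min(f$onset_s)) / epoch_s)
  as.numeric(tapply(f[[column]], ep, mean))
}

#' Control vs head-down-tilt morphology comparison
#'
#' Condition means of P1 and P2 (shoulder-derived P2 included), the BL%
#' change of each, and a paired t test on per-epoch mean amplitudes
#' (control epoch i paired with HDT epoch i, extra epochs dropped). A P2
#' elevation flag is set when the P2 BL% is positive — the tilt-typical
#' compliance response.
#'
#' @param features_control,features_hdt `pulse_features` data frames for the
#'   same channel under the two conditions; each needs at least 5 classified
#'   beats.
#' @param epoch_s epoch length for the paired units.
#' @return An object of class `hdt_result`: list with `control`, `hdt`
#'   (each `mean_p1`, `mean_p2`, `n_beats`), `p1_bl_percent`,
#'   `p2_bl_percent`, `p1_test`, `p2_test`, `p2_elevated`.
#' @export
compare_hdt <- function(features_control, features_hdt, epoch_s = 10) {
  nc <- sum(!is.na(features_control$morph_class))
  nh <- sum(!is.na(features_hdt$morph_class))
  if (nc < 5 || nh < 5) {
    stop_regwave("need >= 5 classified beats per condition (control ", nc,
                 ", HDT ", nh, ")")
  }
  sc <- summarize_epoch(features_control)
  sh <- summarize_epoch(features_hdt)
  pair_up <- function(column) {
    x <- epoch_means_of(features_control, column, epoch_s)
    y <- epoch_means_of(features_hdt, column, epoch_s)
    m <- min(length(x), length(y))
    if (m < 2) return(NULL)
    paired_test(y[seq_len(m)], x[seq_len(m)])
  }
  p2_bl <- baseline_percent(sc$mean_p2, sh$mean_p2)
  structure(list(
    control = list(mean_p1 = sc$mean_p1, mean_p2 = sc$mean_p2,
                   n_beats = sc$n_beats),
    hdt = list(mean_p1 = sh$mean_p1, mean_p2 = sh$mean_p2,
               n_beats = sh$n_beats),
    p1_bl_percent = baseline_percent(sc$mean_p1, sh$mean_p1),
    p2_bl_percent = p2_bl,
    p1_test = pair_up("p1_amp"),
    p2_test = pair_up("p2_amp"),
    p2_elevated = p2_bl > 0),
    class = "hdt_result")
}

#' @export
print.hdt_result <- function(x, ...) {
  cat(sprintf("<hdt_result> P1 %.3f -> %.3f (%+.2f BL%%), P2 %.3f -> %.3f (%+.2f BL%%)%s\n",
              x$control$mean_p1, x$hdt$mean_p1, x$p1_bl_percent,
              x$control$mean_p2, x$hdt$mean_p2, x$p2_bl_percent,
              if (isTRUE(x$p2_elevated)) " [P2 elevated]" else ""))
  if (!is.null(x$p2_test)) {
    cat(sprintf("  P2 paired t: t = %.3f, p = %.3g (n = %d epochs)\n",
                x$p2_test$statistic, x$p2_test$p_value, x$p2_test$n))
  }
  invisible(x)
}

#' Assemble a session report table
#'
#' One row per recording channel: condition means, BL% changes, and the
#' between-derivation REGx R-squared. A missing arm channel leaves the R²
#' column absent (`NA`), matching the convention that no index is computed
#' without the reference channel.
#'
#' @param hdt_results named list of [compare_hdt()] results, one per channel.
#' @param bh_results optional list of [analyze_breath_hold()] results.
#' @param regx_r2 [compare_derivations()] value, or `NA` when the arm
#'   channel is missing.
#' @param subject optional subject/recording identifier.
#' @return list of class `session_report` with a `table` data frame and a
#'   `breath_holds` data frame.
#' @export
build_report <- function(hdt_results, bh_results = list(), regx_r2 = NA_real_,
                         subject = "session") {
  rows <- lapply(names(hdt_results), function(ch) {
    h <- hdt_results[[ch]]
    data.frame(subject = subject, channel = ch,
               p1_control = h$control$mean_p1, p1_hdt = h$hdt$mean_p1,
               p1_bl_percent = h$p1_bl_percent,
               p2_control = h$control$mean_p2, p2_hdt = h$hdt$mean_p2,
               p2_bl_percent = h$p2_bl_percent,
               p2_p_value = if (!is.null(h$p2_test)) h$p2_test$p_value else NA_real_,
               n_control = h$control$n_beats, n_hdt = h$hdt$n_beats,
               regx_r2 = regx_r2)
  })
  bh <- if (length(bh_results)) {
    do.call(rbind, lapply(seq_along(bh_results), function(i) {
      b <- bh_results[[i]]
      data.frame(subject = subject, bh_start_s = b$bh_start_s,
                 baseline_p1 = b$baseline_p1_mean, max_p1 = b$max_p1,
                 peak_delay_s = b$peak_delay_s, bl_percent = b$bl_percent)
    }))
  } else {
    data.frame(subject = character(0), bh_start_s = numeric(0),
               baseline_p1 = numeric(0), max_p1 = numeric(0),
               peak_delay_s = numeric(0), bl_percent = numeric(0))
  }
  structure(list(table = do.call(rbind, rows), breath_holds = bh),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat("Session report\n==============\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (nrow(x$breath_holds)) {
    cat("\nBreath-holds\n")
    print(x$breath_holds, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Run the full pipeline on an annotated session recording
#'
#' Convenience end-to-end driver: smooths the recording, detects artifacts,
#' extracts per-beat features on the head channels, splits them into control
#' and head-down-tilt periods using the posture annotations, analyses every
#' annotated breath-hold, computes REGx for both head derivations against
#' the arm channel, and assembles the report. Annotation labels follow the
#' [generate_session()] conventions (`BH_START`/`BH_END`, `POSTURE_HDT`).
#'
#' @param record an annotated [signal_record()] with channels `bifrontal`,
#'   `bitemporal` and optionally `arm`.
#' @param head_channels head channel labels.
#' @param arm_channel reference channel label or `NULL`.
#' @param window_s,update_s,min_pairs moving-correlation settings.
#' @return list with `features` (per channel), `mask`, `bh` (per channel list
#'   of [analyze_breath_hold()] results), `hdt` (per channel
#'   [compare_hdt()]), `regx` (per head channel `regx_series`), `regx_r2`,
#'   and `report`.
#' @export
analyze_session <- function(record,
                            head_channels = c("bifrontal", "bitemporal"),
                            arm_channel = "arm",
                            window_s = 300, update_s = 10, min_pairs = 20) {
  sm <- smooth_running_average(record)
  mask <- detect_artifacts(sm)
  ann <- record$annotations
  hdt_start <- ann$time_s[ann$label == "POSTURE_HDT"][1]
  bh_starts <- ann$time_s[ann$label == "BH_START"]
  bh_ends <- ann$time_s[ann$label == "BH_END"]

  features <- lapply(stats::setNames(head_channels, head_channels),
                     function(ch) extract_all_features(sm, ch, mask = mask))
  in_bh_response <- function(t) {
    length(bh_starts) && any(t >= bh_starts - 5 & t <= bh_ends + 60)
  }
  hdt <- lapply(features, function(f) {
    quiet <- !vapply(f$onset_s, in_bh_response, logical(1))
    if (is.na(hdt_start)) return(NULL)
    compare_hdt(f[quiet & f$onset_s < hdt_start, ],
                f[quiet & f$onset_s >= hdt_start, ])
  })
  bh <- lapply(features, function(f) {
    lapply(seq_along(bh_starts), function(i) {
      analyze_breath_hold(f, list(start_s = bh_starts[i],
                                  duration_s = bh_ends[i] - bh_starts[i]))
    })
  })
  regx <- NULL
  regx_r2 <- NA_real_
  if (!is.null(arm_channel) && arm_channel %in% record$channel_labels) {
    arm_ep <- epoch_average(sm, arm_channel, mask = mask)
    regx <- lapply(stats::setNames(head_channels, head_channels), function(ch) {
      moving_correlation(epoch_average(sm, ch, mask = mask), arm_ep,
                         window_s = window_s, update_s = update_s,
                         min_pairs = min_pairs)
    })
    if (length(regx) >= 2) {
      regx_r2 <- tryCatch(compare_derivations(regx[[1]], regx[[2]]),
                          error = function(e) NA_real_)
    }
  }
  report <- build_report(Filter(Negate(is.null), hdt),
                         bh_results = bh[[1]], regx_r2 = regx_r2)
  list(features = features, mask = mask, bh = bh, hdt = hdt,
       regx = regx, regx_r2 = regx_r2, report = report)
}
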