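#' Fixed-epoch averaging of a channel
#'
#' Reduces a channel to one scalar per consecutive `epoch_s`-second epoch —
#' the "time-averaged values" that feed the moving-correlation index. The
#' default feature is the epoch mean of the (smoothed) signal; the
#' `"pulse_amplitude"` alternative uses a robust per-epoch pulse amplitude
#' (95th minus 5th percentile), for the reading in which the channels are
#' compared by pulsatile amplitude rather than mean level. Samples under an
#' [artifact_mask()] are excluded; an epoch with fewer than half of its
#' samples clean is marked invalid.
#'
#' @param record a [signal_record()].
#' @param channel channel label or index.
#' @param epoch_s epoch length in seconds (default 10).
#' @param mask optional [artifact_mask()].
#' @param feature `"mean"` (default) or `"pulse_amplitude"`.
#' @return An object of class `epoch_series`: list with `epoch_s`, `times`
#'   (epoch centers, seconds), `values`, `valid`.
#' @export
epoch_average <- function(record, channel, epoch_s = 10, mask = NULL,
                          feature = c("mean", "pulse_amplitude")) {
  feature <- match.arg(feature)
  if (duration_s(record) < epoch_s) {
    stop_regwave("record shorter than one epoch")
  }
  x <- get_channel(record, channel)
  fs <- record$fs
  spe <- round(epoch_s * fs)
  n_ep <- floor(length(x) / spe)
  ok <- if (is.null(mask)) rep(TRUE, length(x)) else {
    mask_validity(mask, length(x), fs)
  }
  values <- numeric(n_ep)
  valid <- logical(n_ep)
  for (i in seq_len(n_ep)) {
    idx <- ((i - 1) * spe + 1):(i * spe)
    good <- ok[idx]
    if (mean(good) < 0.5) {
      values[i] <- NA_real_
      valid[i] <- FALSE
    } else {
      xi <- x[idx][good]
      values[i] <- if (feature == "mean") mean(xi) else {
        diff(stats::quantile(xi, c(0.05, 0.95), names = FALSE))
      }
      valid[i] <- TRUE
    }
  }
  structure(list(epoch_s = epoch_s,
                 times = (seq_len(n_ep) - 0.5) * epoch_s,
                 values = values, valid = valid),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %d epochs of %g s (%d valid)\n",
              length(x$values), x$epoch_s, sum(x$valid)))
  invisible(x)
}

#' Moving Pearson correlation (REGx / PRx)
#'
#' The autoregulation index: for each emit time `t` (starting at exactly
#' `window_s` and stepping by `update_s`), the Pearson correlation of the two
#' epoch series over the valid epoch pairs whose centers fall in
#' `(t - window_s, t]`. With 10-second epochs and a 5-minute window each
#' index value summarises up to 30 paired observations. Values near +1 mean
#' the head and reference channels co-fluctuate passively (impaired
#' autoregulation); values near -1 mean inverse coupling (active, intact
#' autoregulation). Windows with fewer than `min_pairs` valid pairs, or in
#' which either series has zero variance (Pearson undefined), are emitted as
#' invalid (`NA`, flagged) rather than forced to a boundary value.
#'
#' @param x,y [epoch_average()] results on the same epoch grid.
#' @param window_s correlation window length in seconds (default 300); must
#'   be a multiple of the epoch length.
#' @param update_s emission interval in seconds, between 10 and 60.
#' @param min_pairs minimum number of valid epoch pairs per window.
#' @return An object of class `regx_series`: list with `times`, `values`
#'   (in `[-1, 1]` where valid), `n_pairs`, `valid`, `window_s`, `update_s`.
#' @examples
#' rec <- generate_sine_pair(10, 1, 200, 400)
#' e1 <- epoch_average(rec, "head"); e2 <- epoch_average(rec, "arm")
#' moving_correlation(e1, e2)$values[1] # +1: identical channels
#' @export
moving_correlation <- function(x, y, window_s = 300, update_s = 10,
                               min_pairs = 20) {
  stopifnot(inherits(x, "epoch_series"), inherits(y, "epoch_series"))
  if (x$epoch_s != y$epoch_s || length(x$values) != length(y$values)) {
    stop_regwave("epoch series must share the same epoch grid")
  }
  epoch_s <- x$epoch_s
  if (abs(window_s / epoch_s - round(window_s / epoch_s)) > 1e-9) {
    stop_regwave("window_s must be a multiple of the epoch length")
  }
  if (update_s < 10 || update_s > 60) {
    stop_regwave("update_s must be between 10 and 60 seconds")
  }
  total_s <- length(x$values) * epoch_s
  if (total_s < window_s) {
    return(structure(list(times = numeric(0), values = numeric(0),
                          n_pairs = integer(0), valid = logical(0),
                          window_s = window_s, update_s = update_s),
                     class = "regx_series"))
  }
  emit <- seq(window_s, total_s, by = update_s)
  values <- rep(NA_real_, length(emit))
  n_pairs <- integer(length(emit))
  valid <- logical(length(emit))
  for (k in seq_along(emit)) {
    t <- emit[k]
    in_win <- x$times > t - window_s & x$times <= t
    pair_ok <- in_win & x$valid & y$valid
    n <- sum(pair_ok)
    n_pairs[k] <- n
    if (n < max(min_pairs, 2)) next
    xv <- x$values[pair_ok]
    yv <- y$values[pair_ok]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) next
    values[k] <- stats::cor(xv, yv)
    valid[k] <- TRUE
  }
  structure(list(times = emit, values = values, n_pairs = n_pairs,
                 valid = valid, window_s = window_s, update_s = update_s),
            class = "regx_series")
}

#' @export
print.regx_series <- function(x, ...) {
  cat(sprintf("<regx_series> %d values, window %g s, update %g s (%d valid)\n",
              length(x$values), x$window_s, x$update_s, sum(x$valid)))
  if (any(x$valid)) {
    cat(sprintf("  range of valid values: [%.3f, %.3f]\n",
                min(x$values[x$valid]), max(x$values[x$valid])))
  }
  invisible(x)
}

#' Plot a moving-correlation trace
#' @param x a `regx_series`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.regx_series <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", ylim = c(-1, 1),
                 xlab = "time (s)", ylab = "moving correlation", ...)
  graphics::abline(h = 0, col = "grey60", lty = 2)
  invisible(x)
}

#' Classify autoregulation state from an index value
#'
#' Negative index: inverse head/reference coupling, autoregulation actively
#' countering pressure changes (`ACTIVE`). Non-negative: passive transmission
#' (`PASSIVE`); the tie at exactly 0 is classed `PASSIVE`, conservative
#' toward impairment. `NA` values propagate as unclassified.
#'
#' @param value numeric vector of index values in `[-1, 1]`.
#' @return character vector `"ACTIVE"` / `"PASSIVE"` / `NA`.
#' @export
classify_ar <- function(value) {
  if (any(abs(value) > 1 + 1e-12, na.rm = TRUE)) {
    stop_regwave("index values must lie in [-1, 1]")
  }
  ifelse(is.na(value), NA_character_,
         ifelse(value < 0, "ACTIVE", "PASSIVE"))
}

#' Agreement between two index derivations
#'
#' Squared Pearson correlation between two moving-correlation traces (e.g.
#' bifrontal-derived vs bitemporal-derived REGx) over their common valid emit
#' times — the R-squared used to report how closely the two derivations track
#' each other across a full recording.
#'
#' @param a,b `regx_series` objects on overlapping emit grids.
#' @return numeric scalar in `[0, 1]`.
#' @export
compare_derivations <- function(a, b) {
  common <- intersect(a$times, b$times)
  ia <- match(common, a$times)
  ib <- match(common, b$times)
  ok <- a$valid[ia] & b$valid[ib]
  if (sum(ok) < 3) {
    stop_regwave("need at least 3 common valid index samples (have ",
                 sum(ok), ")")
  }
  stats::cor(a$values[ia][ok], b$values[ib][ok])^2
}
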