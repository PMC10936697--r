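# Internal numerical helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Centered running mean over exactly `n` samples in the interior; edges use a
# shrinking window so the output has the same length as the input. For even n
# the window covers offsets [-(floor((n-1)/2)), +(n-1-floor((n-1)/2))].
running_mean <- function(x, n) {
  stopifnot(n >= 1, n <= length(x))
  if (n == 1) return(as.numeric(x))
  N <- length(x)
  left <- floor((n - 1) / 2)
  right <- n - 1 - left
  # Interior: per-window sums via convolution (no cumulative error growth).
  out <- as.numeric(stats::filter(x, rep(1 / n, n), sides = 2))
  if (right > left) {
    # stats::filter centres odd windows; even windows need a half-step shift
    # so that out[i] = mean(x[(i-left):(i+right)]).
    out <- c(out[-1], NA_real_)
  }
  idx <- which(is.na(out))
  if (length(idx)) {
    lo <- pmax(idx - left, 1)
    hi <- pmin(idx + right, N)
    cs <- cumsum(c(0, x))
    out[idx] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out
}

# Strict local maxima with deterministic plateau handling: a plateau counts as
# one maximum located at its first sample. Endpoints are never maxima.
# Prominence of a peak: height above the higher of the two valley floors
# encountered before reaching a taller sample (or the record edge) on each side.
local_maxima <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- integer(0)
  for (j in 2:(k - 1)) {
    if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1]) {
      cand <- c(cand, starts[j])
    }
  }
  if (!length(cand) || min_prominence <= 0) return(cand)
  keep <- vapply(cand, function(i) {
    peak <- x[i]
    lmin <- peak
    j <- i - 1
    while (j >= 1 && x[j] <= peak) { lmin <- min(lmin, x[j]); j <- j - 1 }
    rmin <- peak
    j <- i + 1
    while (j <= n && x[j] <= peak) { rmin <- min(rmin, x[j]); j <- j + 1 }
    (peak - max(lmin, rmin)) >= min_prominence
  }, logical(1))
  cand[keep]
}

local_minima <- function(x, min_prominence = 0) {
  local_maxima(-x, min_prominence = min_prominence)
}

# Enforce a refractory distance between detected extrema: deepest/tallest
# first, suppress any later candidate within `min_distance` samples of an
# accepted one. `taken` is kept sorted so neighbour checks are O(log n).
enforce_min_distance <- function(idx, height, min_distance) {
  if (length(idx) <= 1) return(idx)
  ord <- order(height, decreasing = TRUE, idx)
  taken <- numeric(0)
  for (i in ord) {
    pos <- findInterval(idx[i], taken)
    ok <- !(pos >= 1 && idx[i] - taken[pos] < min_distance) &&
      !(pos < length(taken) && taken[pos + 1] - idx[i] < min_distance)
    if (ok) taken <- append(taken, idx[i], after = pos)
  }
  as.integer(taken)
}

# 32-bit FNV-1a over a raw vector; used for config/input digests in run logs.
# State kept as a double < 2^32; the modular multiply is split into 16-bit
# halves so every intermediate stays within exact double range.
fnv1a32 <- function(raw) {
  h <- 2166136261
  p <- 16777619
  for (b in as.integer(raw)) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), b)
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_regwave <- function(...) stop(..., call. = FALSE)
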