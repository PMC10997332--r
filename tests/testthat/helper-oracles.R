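# Independent brute-force oracles used to pin down the fast implementations.

# Per-sample windowed percentile (centered, truncated at edges), computed
# with stats::quantile directly.
oracle_running_percentile <- function(x, fs_hz, window_s, p) {
  n <- length(x)
  half <- round(window_s * fs_hz) %/% 2L
  vapply(seq_len(n), function(i) {
    win <- x[max(1L, i - half):min(n, i + half)]
    quantile(win, p, type = 7, names = FALSE)
  }, numeric(1))
}

# Per-sample scan implementing the threshold-crossing rule and the
# pre-window exclusion rule literally.
oracle_detect_onsets <- function(primary, other, fs_hz, threshold = 30,
                                 exclusion_window_s = 3, quiescence = 1,
                                 type = "loco_closed") {
  n <- length(primary)
  w <- round(exclusion_window_s * fs_hz)
  time_s <- numeric(0); valid <- logical(0); reason <- character(0)
  for (i in seq_len(n)[-1]) {
    if (primary[i] >= threshold && primary[i - 1] < threshold) {
      if (i - w < 1) {
        v <- FALSE; rs <- "incomplete pre-window"
      } else {
        active <- FALSE
        for (j in (i - w):(i - 1)) {
          if (primary[j] > quiescence || other[j] > quiescence) {
            active <- TRUE
            break
          }
        }
        if (active) { v <- FALSE; rs <- "activity in pre-window" }
        else { v <- TRUE; rs <- "" }
      }
      time_s <- c(time_s, (i - 1) / fs_hz)
      valid <- c(valid, v)
      reason <- c(reason, rs)
    }
  }
  data.frame(time_s = time_s, type = rep(type, length(time_s)),
             valid = valid, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

# Exact rank-sum null distribution by explicit enumeration over all
# assignments of the pooled midranks.
oracle_rank_sum_p <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  Wdist <- apply(utils::combn(N, n), 2L, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(Wdist <= W + 1e-9), mean(Wdist >= W - 1e-9)))
}
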