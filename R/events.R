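#' Detect locomotion or visual-flow onsets by threshold crossing
#'
#' An onset candidate is the first sample at or above `threshold_cms` after a
#' sample below it (upward crossing; no sub-sample interpolation). A candidate
#' is valid only if neither the primary nor the other behavior trace shows any
#' activity (speed above `quiescence_cms`) anywhere in the
#' `exclusion_window_s` seconds preceding the onset sample; candidates whose
#' pre-window extends past the session start are marked invalid. Invalid
#' candidates are retained with their exclusion reason. For visual-flow
#' onsets, pass the flow trace as `primary_speed` and the locomotion trace as
#' `other_speed`: the same rule then restricts onsets to times when the mouse
#' was not locomoting.
#'
#' @param primary_speed Trace (cm/s) whose threshold crossings define onsets.
#' @param other_speed Companion trace (cm/s) that must also be quiescent in
#'   the pre-window; same sampling and length.
#' @param fs_hz Sampling rate in Hz.
#' @param threshold_cms Onset speed threshold; default 30 cm/s.
#' @param exclusion_window_s Pre-onset window that must be quiescent; default
#'   3 s (1 s is the variant used for eGFP recordings).
#' @param quiescence_cms Speed above which a trace counts as active in the
#'   pre-window; default 1 cm/s.
#' @param type Event-type label stored in the table (e.g. `"loco_closed"`,
#'   `"loco_open"`, `"flow_open"`).
#' @return `data.frame` of class `cf_events` with columns `time_s`, `type`,
#'   `valid`, `exclusion_reason`, sorted by time.
#' @export
detect_onsets <- function(primary_speed, other_speed, fs_hz,
                          threshold_cms = 30, exclusion_window_s = 3,
                          quiescence_cms = 1, type = "loco_closed") {
  if (length(primary_speed) != length(other_speed))
    stop("primary and other traces differ in length", call. = FALSE)
  stopifnot(fs_hz > 0, threshold_cms > 0, exclusion_window_s > 0)
  n <- length(primary_speed)
  w <- round(exclusion_window_s * fs_hz)

  cand <- which(primary_speed[-1L] >= threshold_cms &
                primary_speed[-n] < threshold_cms) + 1L
  act <- (primary_speed > quiescence_cms) | (other_speed > quiescence_cms)
  cum <- c(0, cumsum(act))

  valid <- logical(length(cand))
  reason <- character(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    if (i - w < 1L) {
      reason[j] <- "incomplete pre-window"
    } else if (cum[i] - cum[i - w] > 0) {
      reason[j] <- "activity in pre-window"
    } else valid[j] <- TRUE
  }
  out <- data.frame(time_s = (cand - 1L) / fs_hz,
                    type = rep(type, length(cand)), valid = valid,
                    exclusion_reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("cf_events", "data.frame")
  out
}

#' Extract event-aligned dF/F snippets
#'
#' Cuts a window around every valid event out of the ROI traces, at the
#' native bin width (10 ms at 100 Hz). Events whose window would extend past
#' the session bounds are dropped (never zero-padded), with the drop count in
#' attribute `"n_dropped"`. Bin `k` covers relative time
#' `[pre + (k-1) dt, pre + k dt)`.
#'
#' @param traces Samples x ROI matrix of dF/F values.
#' @param events A `cf_events` table (only rows with `valid == TRUE` are
#'   used).
#' @param fs_hz Sampling rate in Hz.
#' @param window_s `c(pre, post)` window in seconds relative to onset;
#'   default `c(-5, 3)`.
#' @param mouse,session Labels attached to every onset for hierarchical
#'   resampling downstream.
#' @return A `cf_aligned` object: `data` is an onsets x ROI x bin array,
#'   `onset_info` a `data.frame` of per-onset labels, plus window metadata.
#'   Zero usable events give an empty tensor with a warning, not an error.
#' @export
extract_aligned <- function(traces, events, fs_hz, window_s = c(-5, 3),
                            mouse = "m01", session = "s01") {
  stopifnot(is.matrix(traces), length(window_s) == 2L,
            window_s[1] < window_s[2])
  n <- nrow(traces)
  roi_ids <- colnames(traces)
  pre_b <- round(window_s[1] * fs_hz)
  post_b <- round(window_s[2] * fs_hz)
  nb <- post_b - pre_b

  ev <- events[events$valid %in% TRUE, , drop = FALSE]
  i0 <- round(ev$time_s * fs_hz) + 1L
  lo <- i0 + pre_b
  hi <- i0 + post_b - 1L
  ok <- lo >= 1L & hi <= n
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " event(s) dropped: window exceeds session bounds")
  ev <- ev[ok, , drop = FALSE]
  lo <- lo[ok]

  data <- array(NA_real_, dim = c(nrow(ev), ncol(traces), nb),
                dimnames = list(NULL, roi_ids, NULL))
  for (e in seq_len(nrow(ev)))
    data[e, , ] <- t(traces[lo[e]:(lo[e] + nb - 1L), , drop = FALSE])
  if (nrow(ev) == 0L)
    warning("no usable events in window", call. = FALSE)

  structure(list(
    data = data,
    onset_info = data.frame(mouse = rep(mouse, nrow(ev)),
                            session = rep(session, nrow(ev)),
                            time_s = ev$time_s,
                            type = ev$type, stringsAsFactors = FALSE),
    window_s = window_s, bin_s = 1 / fs_hz, roi_ids = roi_ids,
    baselined = FALSE, baseline_window_s = NULL,
    n_dropped = n_dropped
  ), class = "cf_aligned")
}

#' Combine aligned tensors across sessions
#'
#' @param ... `cf_aligned` objects with identical windows, bins and ROI sets
#'   (or a single list of them).
#' @return One `cf_aligned` with onsets stacked.
#' @export
combine_aligned <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "cf_aligned"))
    parts <- parts[[1]]
  parts <- Filter(function(a) dim(a$data)[1] > 0, parts)
  stopifnot(length(parts) > 0)
  ref <- parts[[1]]
  for (a in parts)
    stopifnot(identical(a$window_s, ref$window_s),
              identical(a$bin_s, ref$bin_s),
              identical(a$roi_ids, ref$roi_ids),
              identical(a$baselined, ref$baselined))
  n_tot <- sum(vapply(parts, function(a) dim(a$data)[1], integer(1)))
  data <- array(NA_real_, dim = c(n_tot, dim(ref$data)[2], dim(ref$data)[3]),
                dimnames = dimnames(ref$data))
  at <- 0L
  for (a in parts) {
    k <- dim(a$data)[1]
    data[at + seq_len(k), , ] <- a$data
    at <- at + k
  }
  ref$data <- data
  ref$onset_info <- do.call(rbind, lapply(parts, `[[`, "onset_info"))
  ref$n_dropped <- sum(vapply(parts, `[[`, numeric(1), "n_dropped"))
  ref
}

baseline_windows <- list(stimulus = c(-0.2, 0),
                         onset_gcamp = c(-2.9, -2.7),
                         onset_egfp = c(-0.9, -0.7))

baseline_bins <- function(aligned, win) {
  nb <- dim(aligned$data)[3]
  starts <- aligned$window_s[1] + (seq_len(nb) - 1L) * aligned$bin_s
  which(starts >= win[1] - 1e-9 & starts + aligned$bin_s <= win[2] + 1e-9)
}

#' Baseline-subtract aligned responses
#'
#' Subtracts, per onset and ROI, the mean over the mode's baseline window:
#' `(-200, 0)` ms for unpredictable stimuli (mismatch, grating onsets),
#' `(-2900, -2700)` ms for locomotion/flow onsets in GCaMP recordings
#' (accommodating indicator offset dynamics and anticipatory activity), or
#' `(-900, -700)` ms for eGFP recordings. After subtraction the mean over
#' that window is exactly zero, making the operation idempotent.
#'
#' @param aligned A `cf_aligned` object.
#' @param mode `"stimulus"`, `"onset_gcamp"` or `"onset_egfp"`.
#' @return The baselined `cf_aligned`.
#' @export
baseline_subtract <- function(aligned,
                              mode = c("onset_gcamp", "stimulus",
                                       "onset_egfp")) {
  mode <- match.arg(mode)
  win <- baseline_windows[[mode]]
  if (win[1] < aligned$window_s[1] - 1e-9 ||
      win[2] > aligned$window_s[2] + 1e-9)
    stop("baseline window for mode '", mode, "' (", win[1], ", ", win[2],
         ") s lies outside the aligned window", call. = FALSE)
  bins <- baseline_bins(aligned, win)
  stopifnot(length(bins) > 0)
  if (dim(aligned$data)[1] > 0) {
    base <- apply(aligned$data[, , bins, drop = FALSE], c(1, 2), mean)
    aligned$data <- aligned$data - as.vector(base)  # recycles over bins
  }
  aligned$baselined <- TRUE
  aligned$baseline_window_s <- win
  aligned$baseline_mode <- mode
  aligned
}

#' Event-triggered average with hierarchical-bootstrap band
#'
#' Pools all onsets into a per-ROI, per-bin mean and attaches a 90%
#' hierarchical-bootstrap confidence band (resampling first over mice, then
#' over onsets within each selected mouse, per 10-ms time bin). With a single
#' mouse, the band degrades to an onset-level bootstrap with a warning.
#'
#' @param aligned A `cf_aligned` (normally baselined).
#' @param n_boot Bootstrap replicates per band; default 1000.
#' @param ci Confidence level; default 0.90.
#' @param share_indices If `TRUE` (default) one resampling is shared across
#'   all bins of a replicate, so bands are trace-coherent.
#' @return A `cf_triggered` object: `mean`, `ci_low`, `ci_high` (ROI x bin),
#'   `time_s` bin start times, `n_onsets`, `n_mice`.
#' @export
triggered_average <- function(aligned, n_boot = 1000, ci = 0.90,
                              share_indices = TRUE) {
  stopifnot(inherits(aligned, "cf_aligned"), dim(aligned$data)[1] > 0)
  mice <- aligned$onset_info$mouse
  if (length(unique(mice)) < 2L) {
    warning("single mouse: falling back to onset-level bootstrap",
            call. = FALSE)
    mice <- as.character(seq_along(mice))
  }
  mu <- apply(aligned$data, c(2, 3), mean)
  nb <- dim(aligned$data)[3]
  probs <- c((1 - ci) / 2, 1 - (1 - ci) / 2)
  ci_low <- ci_high <- matrix(NA_real_, nrow(mu), nb,
                              dimnames = dimnames(mu))
  ord <- order(mice)
  grp <- group_offsets(mice[ord])
  for (r in seq_len(nrow(mu))) {
    vals <- aligned$data[ord, r, , drop = FALSE]
    dim(vals) <- c(length(ord), nb)
    reps <- if (share_indices) {
      hboot_matrix_cpp(vals, grp$start, grp$n, n_boot)
    } else {
      vapply(seq_len(nb), function(b)
        hboot_means_cpp(vals[, b], rep(1L, nrow(vals)), grp$start, grp$n,
                        n_boot), numeric(n_boot))
    }
    q <- apply(reps, 2L, quantile, probs = probs, names = FALSE)
    # band is taken to include the pooled point estimate
    ci_low[r, ] <- pmin(q[1, ], mu[r, ])
    ci_high[r, ] <- pmax(q[2, ], mu[r, ])
  }
  structure(list(mean = mu, ci_low = ci_low, ci_high = ci_high,
                 time_s = aligned$window_s[1] +
                   (seq_len(nb) - 1L) * aligned$bin_s,
                 window_s = aligned$window_s, bin_s = aligned$bin_s,
                 roi_ids = aligned$roi_ids,
                 n_onsets = dim(aligned$data)[1],
                 n_mice = length(unique(aligned$onset_info$mouse)),
                 ci = ci, n_boot = n_boot),
            class = "cf_triggered")
}

# start offsets (0-based) and unit counts per level-1 group of a sorted
# label vector; units here are individual rows
group_offsets <- function(sorted_labels) {
  r <- rle(sorted_labels)
  n <- r$lengths
  list(start = as.integer(cumsum(c(0L, n[-length(n)]))), n = as.integer(n))
}

#' Average response map from a pixel movie
#'
#' Per-pixel baseline-subtracted mean response over an averaging window
#' across events (e.g. the mismatch response map).
#'
#' @param movie 3-D array time x rows x cols of dF/F values.
#' @param events A `cf_events` table (valid rows used); at least one event
#'   must have both windows in bounds.
#' @param fs_hz Sampling rate in Hz.
#' @param avg_window_s Averaging window relative to onset; default `c(0, 1)`.
#' @param baseline_window_s Baseline window; default `c(-0.2, 0)` (the
#'   unpredictable-stimulus window).
#' @return rows x cols matrix of mean responses.
#' @export
response_map <- function(movie, events, fs_hz, avg_window_s = c(0, 1),
                         baseline_window_s = c(-0.2, 0)) {
  stopifnot(length(dim(movie)) == 3L)
  n <- dim(movie)[1]
  ev <- events[events$valid %in% TRUE, , drop = FALSE]
  acc <- matrix(0, dim(movie)[2], dim(movie)[3])
  used <- 0L
  for (t0 in ev$time_s) {
    i0 <- round(t0 * fs_hz) + 1L
    bi <- (i0 + round(baseline_window_s[1] * fs_hz)):
          (i0 + round(baseline_window_s[2] * fs_hz) - 1L)
    ai <- (i0 + round(avg_window_s[1] * fs_hz)):
          (i0 + round(avg_window_s[2] * fs_hz) - 1L)
    if (min(bi, ai) < 1L || max(bi, ai) > n) next
    base <- apply(movie[bi, , , drop = FALSE], c(2, 3), mean)
    resp <- apply(movie[ai, , , drop = FALSE], c(2, 3), mean)
    acc <- acc + (resp - base)
    used <- used + 1L
  }
  if (used == 0L) stop("no usable events for response map", call. = FALSE)
  acc / used
}

#' Linear sum of two onset-aligned responses, mouse-wise
#'
#' Averages each aligned tensor per mouse, sums the two per-mouse means, and
#' reports the across-mouse mean with its SEM over mice (used to test whether
#' a response equals the sum of two component responses).
#'
#' @param aligned_a,aligned_b `cf_aligned` objects with identical ROI sets,
#'   windows and bins, and the same set of mice.
#' @return A list of class `cf_linear_sum` with `mean`, `sem` (ROI x bin),
#'   `per_mouse` (mouse x ROI x bin array) and `mice`.
#' @export
linear_sum <- function(aligned_a, aligned_b) {
  stopifnot(inherits(aligned_a, "cf_aligned"),
            inherits(aligned_b, "cf_aligned"),
            identical(aligned_a$roi_ids, aligned_b$roi_ids),
            identical(aligned_a$window_s, aligned_b$window_s),
            identical(aligned_a$bin_s, aligned_b$bin_s))
  ma <- sort(unique(aligned_a$onset_info$mouse))
  mb <- sort(unique(aligned_b$onset_info$mouse))
  if (!identical(ma, mb))
    stop("mouse sets differ: only in a: ",
         paste(setdiff(ma, mb), collapse = ", "), "; only in b: ",
         paste(setdiff(mb, ma), collapse = ", "), call. = FALSE)
  nr <- dim(aligned_a$data)[2]; nb <- dim(aligned_a$data)[3]
  per_mouse <- array(NA_real_, dim = c(length(ma), nr, nb),
                     dimnames = list(ma, aligned_a$roi_ids, NULL))
  for (m in seq_along(ma)) {
    sa <- aligned_a$onset_info$mouse == ma[m]
    sb <- aligned_b$onset_info$mouse == ma[m]
    per_mouse[m, , ] <-
      apply(aligned_a$data[sa, , , drop = FALSE], c(2, 3), mean) +
      apply(aligned_b$data[sb, , , drop = FALSE], c(2, 3), mean)
  }
  mu <- apply(per_mouse, c(2, 3), mean)
  sem <- apply(per_mouse, c(2, 3), sd) / sqrt(length(ma))
  structure(list(mean = mu, sem = sem, per_mouse = per_mouse, mice = ma),
            class = "cf_linear_sum")
}
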