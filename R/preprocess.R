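#' Median-normalized dF/F
#'
#' Converts a raw fluorescence trace to dF/F with the baseline F0 defined as
#' the median fluorescence of the whole recording, so the output has median
#' exactly zero and is invariant to a positive gain applied to the raw trace.
#'
#' @param raw Numeric vector of raw fluorescence values (> 1 sample).
#' @return Numeric dF/F vector (dimensionless fraction), same length.
#' @export
#' @examples
#' compute_dff(c(1, 1, 3))  # F0 = 1 -> c(0, 0, 2)
compute_dff <- function(raw) {
  if (!is.numeric(raw) || length(raw) < 2L)
    stop("raw trace must be numeric with more than one sample", call. = FALSE)
  if (any(!is.finite(raw)))
    stop("raw trace contains non-finite values", call. = FALSE)
  f0 <- median(raw)
  if (!(f0 > 0)) stop("nonpositive baseline", call. = FALSE)
  (raw - f0) / f0
}

#' Running-percentile drift correction
#'
#' Subtracts a slow baseline estimated as the running 8th percentile of a
#' centered moving window (62.5 s by default; the two-photon variant uses
#' 15 s), truncated at the session edges. The percentile is the
#' linear-interpolation quantile (`stats::quantile` type 7), so the output
#' equals a per-sample windowed-quantile computation exactly.
#'
#' @param x Numeric dF/F trace.
#' @param fs_hz Sampling rate in Hz.
#' @param window_s Moving-window length in seconds.
#' @param percentile Percentile as a fraction in (0, 1); default 0.08.
#' @return Detrended trace `x - baseline`, with the baseline in attribute
#'   `"baseline"`.
#' @export
percentile_detrend <- function(x, fs_hz, window_s = 62.5, percentile = 0.08) {
  stopifnot(is.numeric(x), is.numeric(fs_hz), fs_hz > 0,
            percentile > 0, percentile < 1)
  n <- length(x)
  w <- round(window_s * fs_hz)
  if (w < 2) stop("window must span at least 2 samples", call. = FALSE)
  if (w > n) stop("detrend window (", window_s,
                  " s) is longer than the trace", call. = FALSE)
  half <- w %/% 2L
  baseline <- running_percentile_cpp(as.numeric(x), half, percentile)
  out <- x - baseline
  attr(out, "baseline") <- baseline
  out
}

#' Session-level preprocessing: dF/F and drift correction
#'
#' Applies [compute_dff()] and (optionally) [percentile_detrend()] to every
#' ROI trace of a session with raw-fluorescence units.
#'
#' @param session A `cf_session` with `meta$units == "raw"`.
#' @param window_s,percentile Passed to [percentile_detrend()].
#' @param detrend If `FALSE`, only dF/F conversion is applied.
#' @return The session with dF/F traces (`meta$units == "dff"`).
#' @export
preprocess_session <- function(session, window_s = 62.5, percentile = 0.08,
                               detrend = TRUE) {
  stopifnot(inherits(session, "cf_session"))
  if (!identical(session$meta$units, "raw"))
    stop("session traces are not raw fluorescence (units: ",
         session$meta$units, ")", call. = FALSE)
  fs <- session$meta$fs_hz
  traces <- session$traces
  for (j in seq_len(ncol(traces))) {
    v <- compute_dff(traces[, j])
    if (detrend)
      v <- as.numeric(percentile_detrend(v, fs, window_s, percentile))
    traces[, j] <- v
  }
  session$traces <- traces
  session$meta$units <- "dff"
  session$meta$detrended <- isTRUE(detrend)
  session
}

#' Seizure-like session exclusion
#'
#' Excludes a session if the across-ROI mean dF/F stays above `level`
#' continuously for strictly more than `min_duration_s` (strict reading of
#' "more than": an event of exactly `min_duration_s` is kept). The decision
#' uses integer sample counts, so it is exact and invariant to ROI ordering.
#'
#' @param sessions List of `cf_session` objects with dF/F traces and the full
#'   12-ROI complement.
#' @param level Mean dF/F threshold (fraction); default 0.30.
#' @param min_duration_s Minimum supra-threshold duration in seconds that
#'   triggers exclusion (strictly greater); default 10.
#' @param roi_ids Expected ROI complement; defaults to the 12 ROIs of
#'   [default_roi_geometry()].
#' @return `list(kept, excluded, report)` where `report` is a `data.frame`
#'   with one row per session: `session_id`, `excluded`, and the first
#'   offending window (`window_start_s`, `window_end_s`, `NA` if none).
#' @export
qc_exclude_sessions <- function(sessions, level = 0.30, min_duration_s = 10,
                                roi_ids = default_roi_geometry()$roi) {
  stopifnot(is.list(sessions))
  if (inherits(sessions, "cf_session")) sessions <- list(sessions)
  rows <- vector("list", length(sessions))
  keep <- logical(length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    stopifnot(inherits(s, "cf_session"))
    missing_roi <- setdiff(roi_ids, colnames(s$traces))
    if (length(missing_roi))
      stop("session ", s$meta$session_id, " is missing ROI ",
           paste(missing_roi, collapse = ", "), call. = FALSE)
    fs <- s$meta$fs_hz
    m <- rowMeans(s$traces[, roi_ids, drop = FALSE])
    above <- m > level
    r <- rle(above)
    min_len <- round(min_duration_s * fs)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- which(r$values & r$lengths > min_len)
    excluded <- length(bad) > 0L
    keep[i] <- !excluded
    rows[[i]] <- data.frame(
      session_id = s$meta$session_id,
      excluded = excluded,
      window_start_s = if (excluded) (starts[bad[1]] - 1L) / fs else NA_real_,
      window_end_s = if (excluded) ends[bad[1]] / fs else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  list(kept = sessions[keep], excluded = sessions[!keep],
       report = do.call(rbind, rows))
}
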