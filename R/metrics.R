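# Centered moving-average smoothing with edge truncation.
boxcar_smooth <- function(v, width_bins) {
  n <- length(v)
  if (width_bins <= 1L) return(v)
  half <- width_bins %/% 2L
  cs <- cumsum(v)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

#' Closed/open-loop response similarity per ROI
#'
#' Pearson correlation, for each ROI, between the closed-loop and open-loop
#' average onset responses after a centered 1-s moving average, computed over
#' the aligned window (default -5 s to +3 s). The summary reports
#' mean +/- SEM over the 12 cortical regions.
#'
#' @param closed_avg,open_avg `cf_triggered` objects (matching ROI sets,
#'   windows and bins), e.g. from [triggered_average()].
#' @param smooth_s Moving-average width in seconds; default 1.
#' @return `data.frame(roi, r)` with attribute `"summary"` (list with `mean`,
#'   `sem`, `n_roi`). ROIs with zero variance give `NA` with a warning.
#' @export
onset_similarity <- function(closed_avg, open_avg, smooth_s = 1.0) {
  stopifnot(identical(closed_avg$roi_ids, open_avg$roi_ids),
            identical(dim(closed_avg$mean), dim(open_avg$mean)),
            identical(closed_avg$bin_s, open_avg$bin_s))
  wb <- round(smooth_s / closed_avg$bin_s)
  r <- vapply(seq_along(closed_avg$roi_ids), function(i) {
    a <- boxcar_smooth(closed_avg$mean[i, ], wb)
    b <- boxcar_smooth(open_avg$mean[i, ], wb)
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  if (anyNA(r))
    warning("zero-variance response in window: similarity undefined for ",
            paste(closed_avg$roi_ids[is.na(r)], collapse = ", "),
            call. = FALSE)
  out <- data.frame(roi = closed_avg$roi_ids, r = r,
                    stringsAsFactors = FALSE)
  ok <- !is.na(r)
  attr(out, "summary") <- list(mean = mean(r[ok]),
                               sem = sd(r[ok]) / sqrt(sum(ok)),
                               n_roi = sum(ok))
  out
}

#' Per-mouse V1 closed/open similarity
#'
#' For each mouse, averages onsets separately in left and right V1 for the
#' closed and open-loop conditions, correlates the smoothed closed and open
#' curves per hemisphere, and averages the two hemisphere coefficients. Mice
#' whose peak absolute V1 response is below `min_resp` (1% dF/F by default)
#' in either condition are excluded (the correlation is noise without a clear
#' response), as are mice without onsets in one of the conditions.
#'
#' @param closed_aligned,open_aligned `cf_aligned` tensors pooled over the
#'   cohort (baselined), with per-onset mouse labels.
#' @param v1 The two V1 ROI ids.
#' @param min_resp Peak-response exclusion threshold in dF/F fraction.
#' @param smooth_s Moving-average width in seconds.
#' @return `data.frame(mouse, r, excluded, reason)`.
#' @export
per_mouse_v1_similarity <- function(closed_aligned, open_aligned,
                                    v1 = c("V1_L", "V1_R"),
                                    min_resp = 0.01, smooth_s = 1.0) {
  stopifnot(all(v1 %in% closed_aligned$roi_ids),
            all(v1 %in% open_aligned$roi_ids))
  wb <- round(smooth_s / closed_aligned$bin_s)
  mice <- sort(unique(c(closed_aligned$onset_info$mouse,
                        open_aligned$onset_info$mouse)))
  rows <- lapply(mice, function(m) {
    res <- data.frame(mouse = m, r = NA_real_, excluded = TRUE,
                      reason = "", stringsAsFactors = FALSE)
    ic <- closed_aligned$onset_info$mouse == m
    io <- open_aligned$onset_info$mouse == m
    if (!any(ic) || !any(io)) {
      res$reason <- "no onsets in one condition"
      return(res)
    }
    curves <- function(al, sel) {
      vapply(v1, function(roi) {
        idx <- match(roi, al$roi_ids)
        colMeans(matrix(al$data[sel, idx, ], nrow = sum(sel)))
      }, numeric(dim(al$data)[3]))
    }
    cc <- curves(closed_aligned, ic)
    oc <- curves(open_aligned, io)
    if (max(abs(cc)) < min_resp || max(abs(oc)) < min_resp) {
      res$reason <- "response below threshold"
      return(res)
    }
    rh <- vapply(seq_along(v1), function(h)
      cor(boxcar_smooth(cc[, h], wb), boxcar_smooth(oc[, h], wb)),
      numeric(1))
    res$r <- mean(rh)
    res$excluded <- FALSE
    res
  })
  do.call(rbind, rows)
}

#' Correlation between activity and locomotion speed
#'
#' Pearson correlation of each ROI's dF/F trace with the locomotion speed
#' over the full session. A session in which the mouse never moved (constant
#' speed) gives `NA` for every ROI with a warning.
#'
#' @param session A `cf_session` with dF/F traces.
#' @return `data.frame(mouse, session, condition, treatment, roi, r)`.
#' @export
speed_activity_correlation <- function(session) {
  stopifnot(inherits(session, "cf_session"))
  sp <- session$speed
  if (sd(sp) == 0) {
    warning("constant speed trace: correlation undefined", call. = FALSE)
    r <- rep(NA_real_, ncol(session$traces))
  } else {
    r <- as.numeric(cor(sp, session$traces))
  }
  data.frame(mouse = session$meta$mouse_id,
             session = session$meta$session_id,
             condition = session$meta$condition,
             treatment = session$meta$treatment,
             roi = colnames(session$traces), r = r,
             stringsAsFactors = FALSE)
}

#' Aggregate speed-activity correlations to mouse level
#'
#' Averages per-session coefficients to one value per mouse, ROI, condition
#' (and treatment), the unit used for treatment comparisons.
#'
#' @param df Row-bound output of [speed_activity_correlation()].
#' @return Aggregated `data.frame(mouse, condition, treatment, roi, r)`.
#' @export
aggregate_speed_activity <- function(df) {
  aggregate(r ~ mouse + condition + treatment + roi, data = df,
            FUN = mean, na.action = stats::na.omit)
}

#' After-minus-before change in speed-activity correlation
#'
#' @param agg Output of [aggregate_speed_activity()] containing both
#'   treatment labels.
#' @param before,after Treatment labels to difference.
#' @return `data.frame(mouse, condition, roi, delta_r)`.
#' @export
speed_activity_difference <- function(agg, before = "naive",
                                      after = "drug") {
  b <- agg[agg$treatment == before, ]
  a <- agg[agg$treatment == after, ]
  m <- merge(b, a, by = c("mouse", "condition", "roi"),
             suffixes = c("_before", "_after"))
  data.frame(mouse = m$mouse, condition = m$condition, roi = m$roi,
             delta_r = m$r_after - m$r_before, stringsAsFactors = FALSE)
}

#' Pairwise inter-ROI correlations with normalized distances
#'
#' Pearson correlation of dF/F activity over the session for all 66 pairs of
#' the 12 ROIs, with each pair's planar distance normalized by the mouse's
#' bregma-lambda distance. Pairs involving a zero-variance ROI are flagged
#' missing.
#'
#' @param session A `cf_session` with dF/F traces.
#' @param geometry A `cf_geometry` (per-mouse geometry supported by passing a
#'   mouse-specific object).
#' @return `data.frame` of class `cf_paircors` with columns `mouse`,
#'   `session`, `treatment`, `condition`, `roi_a`, `roi_b`, `r`, `d_norm`,
#'   `missing`.
#' @export
pairwise_roi_correlation <- function(session,
                                     geometry = default_roi_geometry()) {
  stopifnot(inherits(session, "cf_session"))
  traces <- session$traces[, geometry$roi, drop = FALSE]
  stopifnot(ncol(traces) == nrow(geometry))
  sds <- apply(traces, 2L, sd)
  C <- suppressWarnings(cor(traces))
  pd <- pair_distances(geometry)
  r <- C[cbind(match(pd$roi_a, geometry$roi), match(pd$roi_b, geometry$roi))]
  miss <- sds[match(pd$roi_a, geometry$roi)] == 0 |
          sds[match(pd$roi_b, geometry$roi)] == 0
  out <- data.frame(mouse = session$meta$mouse_id,
                    session = session$meta$session_id,
                    treatment = session$meta$treatment,
                    condition = session$meta$condition,
                    roi_a = pd$roi_a, roi_b = pd$roi_b,
                    r = ifelse(miss, NA_real_, r),
                    d_norm = pd$d_norm, missing = miss,
                    stringsAsFactors = FALSE)
  class(out) <- c("cf_paircors", "data.frame")
  out
}

#' Correlation-versus-distance density map
#'
#' Bins pairwise correlations against normalized distance on a fixed 40 x 40
#' grid, smooths with a Gaussian filter, and reports the contour level at 50%
#' of the smoothed peak. The smoothing redistributes each bin's mass through
#' an in-grid renormalized kernel, so total mass is conserved exactly; values
#' outside the fixed ranges are clamped into the edge bins so the
#' pre-smoothing grid sums to the number of input pairs.
#'
#' @param pairs A `cf_paircors` table (rows with `missing == TRUE` are
#'   dropped); at least one usable pair required.
#' @param n_bins Grid size per axis; default 40.
#' @param sigma_bins Gaussian smoothing SD in bin units; default 1.
#' @param d_range,r_range Fixed axis ranges for distance and correlation, so
#'   maps are comparable across cohorts.
#' @return A list of class `cf_density`: `grid` (counts, d x r), `smoothed`,
#'   `d_edges`, `r_edges`, `contour_level` (0.5 x smoothed peak),
#'   `peak_density` (smoothed peak), `n_pairs`.
#' @export
correlation_distance_density <- function(pairs, n_bins = 40,
                                         sigma_bins = 1.0,
                                         d_range = c(0, 1.6),
                                         r_range = c(-0.25, 1)) {
  use <- pairs[!(pairs$missing %in% TRUE) & !is.na(pairs$r), , drop = FALSE]
  if (nrow(use) == 0L) stop("no usable pairs", call. = FALSE)
  clamp_bin <- function(x, rng) {
    b <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
    pmin(pmax(b, 1L), n_bins)
  }
  di <- clamp_bin(use$d_norm, d_range)
  ri <- clamp_bin(use$r, r_range)
  grid <- matrix(0, n_bins, n_bins)
  for (i in seq_len(nrow(use))) grid[di[i], ri[i]] <- grid[di[i], ri[i]] + 1

  rad <- ceiling(4 * sigma_bins)
  off <- -rad:rad
  K <- exp(-outer(off^2, off^2, "+") / (2 * sigma_bins^2))
  smoothed <- matrix(0, n_bins, n_bins)
  nz <- which(grid > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(nz))) {
    ci <- nz[i, 1]; cj <- nz[i, 2]
    ii <- ci + off; jj <- cj + off
    oki <- ii >= 1 & ii <= n_bins
    okj <- jj >= 1 & jj <= n_bins
    kk <- K[oki, okj, drop = FALSE]
    smoothed[ii[oki], jj[okj]] <- smoothed[ii[oki], jj[okj]] +
      grid[ci, cj] * kk / sum(kk)
  }
  structure(list(grid = grid, smoothed = smoothed,
                 d_edges = seq(d_range[1], d_range[2], length.out =
                                 n_bins + 1L),
                 r_edges = seq(r_range[1], r_range[2], length.out =
                                 n_bins + 1L),
                 sigma_bins = sigma_bins,
                 contour_level = 0.5 * max(smoothed),
                 peak_density = max(smoothed),
                 n_pairs = nrow(use)),
            class = "cf_density")
}

#' Treatment-induced change in pairwise correlations, short vs long range
#'
#' Per (mouse, ROI pair): correlation coefficients are first averaged over
#' sessions within the before and after sets, then the normalized change
#' `(r_after - r_before) / r_before` is computed and the pair classified as
#' short-range (`d_norm < cutoff`) or long-range (`d_norm >= cutoff`; the
#' boundary is assigned to long range). Pairs with `r_before == 0` are
#' dropped with a warning (the normalization is undefined). Pairs pool across
#' mice as individual data points.
#'
#' @param before,after `cf_paircors` tables (e.g. all pre-treatment and all
#'   post-treatment sessions of a cohort).
#' @param cutoff Short/long split in bregma-lambda units; default 0.9
#'   (approximately 3.8 mm).
#' @return `data.frame` of class `cf_drug_change` with columns `mouse`,
#'   `roi_a`, `roi_b`, `d_norm`, `r_before`, `r_after`, `change`, `range`.
#'   Use [summary.cf_drug_change()] for median/IQR/mean/whisker summaries.
#' @export
drug_change <- function(before, after, cutoff = 0.9) {
  avg <- function(df) {
    use <- df[!(df$missing %in% TRUE) & !is.na(df$r), , drop = FALSE]
    aggregate(cbind(r, d_norm) ~ mouse + roi_a + roi_b, data = use,
              FUN = mean)
  }
  b <- avg(before)
  a <- avg(after)
  m <- merge(b, a, by = c("mouse", "roi_a", "roi_b"),
             suffixes = c("_before", "_after"))
  if (nrow(m) == 0L) stop("no matched (mouse, pair) rows", call. = FALSE)
  zero <- m$r_before == 0
  if (any(zero))
    warning(sum(zero), " pair(s) dropped: zero correlation before treatment",
            call. = FALSE)
  m <- m[!zero, , drop = FALSE]
  out <- data.frame(
    mouse = m$mouse, roi_a = m$roi_a, roi_b = m$roi_b,
    d_norm = m$d_norm_before,
    r_before = m$r_before, r_after = m$r_after,
    change = (m$r_after - m$r_before) / m$r_before,
    range = ifelse(m$d_norm_before >= cutoff, "long", "short"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cf_drug_change", "data.frame")
  out
}

#' Summarize short- and long-range correlation changes
#'
#' @param object A `cf_drug_change` table.
#' @param ... Unused.
#' @return `data.frame` per range class: `n`, `median`, `q1`, `q3`, `mean`,
#'   `whisker_low`, `whisker_high` (1.5 x IQR fences clipped to the data).
#' @export
summary.cf_drug_change <- function(object, ...) {
  do.call(rbind, lapply(split(object$change, object$range), function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               mean = mean(x),
               whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
               whisker_high = max(x[x <= q[3] + 1.5 * iqr]))
  }))
}
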