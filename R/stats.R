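#' Hierarchical (two-stage) bootstrap of the mean
#'
#' Resamples mice with replacement, then level-2 units (sessions or onsets)
#' within each selected mouse with replacement (each selected mouse
#' contributes its own number of units), computes the mean of the pooled
#' resampled values, and repeats `n_boot` times (default 10,000). The
#' confidence interval is the central quantile interval of the replicate
#' means; the one-sided p-values are the tail proportions of replicate means
#' versus zero (replicates exactly equal to zero are split evenly between the
#' tails).
#'
#' @param values Numeric measurements.
#' @param mouse Level-1 (mouse) label per value.
#' @param unit Optional level-2 label per value (session or onset); by
#'   default every value is its own unit. Values sharing a unit are resampled
#'   together.
#' @param n_boot Number of bootstrap replicates.
#' @param ci Confidence level; default 0.90.
#' @param keep_reps If `TRUE`, replicate means are returned in `$reps`.
#' @return A list of class `cf_hboot`: `point` (mean of the data), `ci_low`,
#'   `ci_high`, `p_greater`, `p_less`, `n_boot`, `n_mice`, `ci`.
#' @export
#' @examples
#' set.seed(1)
#' hboot(rnorm(20, 1), mouse = rep(c("a", "b"), each = 10), n_boot = 500)
hboot <- function(values, mouse, unit = NULL, n_boot = 10000, ci = 0.90,
                  keep_reps = FALSE) {
  if (length(values) == 0L) stop("empty sample", call. = FALSE)
  stopifnot(length(mouse) == length(values), n_boot >= 1)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  mouse <- as.character(mouse)
  if (is.null(unit)) unit <- seq_along(values)
  # group by first appearance so results do not depend on label encoding
  midx <- match(mouse, unique(mouse))
  key <- paste(midx, unit, sep = "\r")
  ord <- order(midx, match(key, unique(key)))
  v <- values[ord]; m <- midx[ord]; k <- key[ord]
  u <- !duplicated(k)
  unit_sums <- as.numeric(rowsum(v, k, reorder = FALSE))
  unit_counts <- as.integer(rowsum(rep(1L, length(v)), k, reorder = FALSE))
  grp <- group_offsets(m[u])
  reps <- hboot_means_cpp(unit_sums, unit_counts, grp$start, grp$n,
                          as.integer(n_boot))
  q <- quantile(reps, c((1 - ci) / 2, 1 - (1 - ci) / 2), names = FALSE)
  n_zero <- sum(reps == 0)
  p_greater <- (sum(reps > 0) + 0.5 * n_zero) / n_boot
  out <- list(point = mean(values), ci_low = q[1], ci_high = q[2],
              p_greater = p_greater, p_less = 1 - p_greater,
              n_boot = n_boot, n_mice = length(grp$n), ci = ci)
  if (keep_reps) out$reps <- reps
  structure(out, class = "cf_hboot")
}

#' @export
print.cf_hboot <- function(x, ...) {
  cat(sprintf(
    "<cf_hboot: mean %.4g, %g%% CI [%.4g, %.4g], p>0 %.4g, p<0 %.4g (%d reps, %d mice)>\n",
    x$point, 100 * x$ci, x$ci_low, x$ci_high, x$p_greater, x$p_less,
    x$n_boot, x$n_mice))
  invisible(x)
}

#' Per-bin hierarchical-bootstrap bands for aligned responses
#'
#' Applies the two-stage bootstrap (mice, then onsets) to every 10-ms time
#' bin and ROI of an aligned tensor. By default one resampling is shared
#' across the bins of a replicate so the bands are trace-coherent; with
#' `share_indices = FALSE` every bin is bootstrapped independently and the
#' band at a bin reduces to [hboot()] on that bin's values.
#'
#' @param aligned A `cf_aligned` object with per-onset mouse labels.
#' @param n_boot Replicates; default 1000.
#' @param ci Confidence level; default 0.90.
#' @param share_indices Share resampling indices across bins of a replicate.
#' @return List with `mean`, `ci_low`, `ci_high` (ROI x bin matrices).
#' @export
hboot_timecourse <- function(aligned, n_boot = 1000, ci = 0.90,
                             share_indices = TRUE) {
  tr <- triggered_average(aligned, n_boot = n_boot, ci = ci,
                          share_indices = share_indices)
  list(mean = tr$mean, ci_low = tr$ci_low, ci_high = tr$ci_high)
}

#' Family-wise error adjusted significance threshold
#'
#' Bonferroni-style adjustment `alpha / m` for `m` comparisons (e.g. m = 9
#' genotype groups).
#'
#' @param alpha Nominal level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return Adjusted threshold `alpha / m`.
#' @export
fwe_adjust <- function(alpha, m) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("m must be a positive whole number", call. = FALSE)
  alpha / m
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses midranks for ties. For group sizes up to 10 each, the null
#' distribution of the rank sum is enumerated exactly over all
#' `choose(n + m, n)` assignments; otherwise a normal approximation with tie
#' correction and 0.5 continuity correction is used. The two-sided p-value is
#' twice the smaller tail, capped at 1 (so identical multisets give p = 1).
#'
#' @param x,y Numeric value vectors (both nonempty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default decides by size.
#' @return List with `statistic` (rank sum of `x`), `p`, `method`.
#' @export
#' @examples
#' rank_sum(c(1, 2, 3), c(10, 11, 12))$p  # exact two-sided 0.1
rank_sum <- function(x, y, exact = NULL) {
  stopifnot(length(x) > 0, length(y) > 0)
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  if (is.null(exact)) exact <- n <= 10 && m <= 10
  if (exact) {
    combos <- utils::combn(N, n)
    Wdist <- colSums(matrix(r[combos], nrow = n))
    p_le <- mean(Wdist <= W + 1e-9)
    p_ge <- mean(Wdist >= W - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (N + 1) / 2
    ties <- table(r)
    tiecor <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tiecor)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  list(statistic = W, p = p, method = method)
}

#' One-way ANOVA followed by per-group bootstrap p-values
#'
#' Classical one-way fixed-effects ANOVA across labeled groups (F from
#' between/within mean squares via `anova(lm(...))`), followed by a
#' hierarchical-bootstrap p-value per group for the hypothesis that the
#' group mean differs from zero. Degenerate cases are reported by convention:
#' all groups identical constants give F = 0, p = 1; nonzero between-group
#' variance with zero within-group variance gives F = Inf, p = 0.
#'
#' @param values Numeric measurements.
#' @param group Group label per value (>= 2 groups, each with >= 2 values).
#' @param mouse Optional mouse label per value for the bootstrap stage;
#'   defaults to value-level resampling.
#' @param n_boot Bootstrap replicates per group; default 1000.
#' @return List with `F`, `p_anova`, `df`, and `groups` (a `data.frame` of
#'   per-group mean, `p_greater`, `p_less`).
#' @export
oneway_anova_then_boot <- function(values, group, mouse = NULL,
                                   n_boot = 1000) {
  group <- as.character(group)
  tab <- table(group)
  if (length(tab) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L)) stop("every group needs at least 2 values",
                          call. = FALSE)
  gm <- tapply(values, group, mean)
  ssb <- sum(tab * (gm - mean(values))^2)
  ssw <- sum((values - gm[group])^2)
  df1 <- length(tab) - 1L
  df2 <- length(values) - length(tab)
  if (ssw == 0 && ssb == 0) {
    F <- 0; p <- 1
  } else if (ssw == 0) {
    F <- Inf; p <- 0
  } else {
    a <- anova(lm(values ~ factor(group)))
    F <- a[["F value"]][1]
    p <- a[["Pr(>F)"]][1]
  }
  if (is.null(mouse)) mouse <- seq_along(values)
  groups <- do.call(rbind, lapply(names(tab), function(g) {
    sel <- group == g
    hb <- hboot(values[sel], mouse = mouse[sel], n_boot = n_boot)
    data.frame(group = g, mean = hb$point, p_greater = hb$p_greater,
               p_less = hb$p_less, stringsAsFactors = FALSE)
  }))
  list(F = F, p_anova = p, df = c(df1, df2), groups = groups)
}
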