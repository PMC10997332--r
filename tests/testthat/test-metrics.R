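test_that("onset similarity hits its algebraic limits", {
  set.seed(4)
  mu <- matrix(rnorm(3 * 800), nrow = 3,
               dimnames = list(c("V1_L", "V1_R", "M2_L"), NULL))
  a <- make_triggered(mu)
  same <- onset_similarity(a, a)
  expect_equal(same$r, rep(1, 3), tolerance = 1e-12)
  flip <- make_triggered(-mu)
  expect_equal(onset_similarity(a, flip)$r, rep(-1, 3), tolerance = 1e-12)
  # symmetry
  set.seed(5)
  b <- make_triggered(matrix(rnorm(3 * 800), nrow = 3,
                             dimnames = dimnames(mu)))
  expect_equal(onset_similarity(a, b)$r, onset_similarity(b, a)$r)
})

test_that("onset similarity equals the Pearson formula on smoothed traces", {
  nb <- 800
  ramp <- seq(0, 1, length.out = nb)
  osc <- sin(2 * pi * seq_len(nb) / 50)
  osc <- osc - mean(osc)
  osc <- osc - sum(osc * (ramp - mean(ramp))) /
    sum((ramp - mean(ramp))^2) * (ramp - mean(ramp))  # orthogonalized
  osc <- osc * sd(ramp) / sd(osc)                      # equal power
  a <- make_triggered(matrix(ramp, 1, dimnames = list("V1_L", NULL)))
  b <- make_triggered(matrix(ramp + osc, 1, dimnames = list("V1_L", NULL)))
  got <- onset_similarity(a, b)$r
  # independent per-sample recomputation of the documented centered
  # truncated moving average (halfwidth 50 bins at 10 ms)
  smooth_ref <- function(v) {
    n <- length(v)
    vapply(seq_len(n),
           function(i) mean(v[max(1, i - 50):min(n, i + 50)]), numeric(1))
  }
  want <- cor(smooth_ref(ramp), smooth_ref(ramp + osc))
  expect_equal(got, want, tolerance = 1e-6)

  flat <- make_triggered(matrix(1, 1, nb, dimnames = list("V1_L", NULL)))
  expect_warning(r0 <- onset_similarity(flat, a), "zero-variance")
  expect_true(is.na(r0$r))
})

test_that("per-mouse V1 similarity averages hemispheres and applies the 1%
           response exclusion", {
  mk <- function(amp_by_mouse) {
    vals <- unlist(amp_by_mouse)
    make_aligned_constant(vals, mice = rep(names(amp_by_mouse),
                                           lengths(amp_by_mouse)),
                          n_roi = 2)
  }
  a <- mk(list(m1 = c(0.05, 0.05), m2 = c(0.04, 0.04)))
  a$roi_ids <- c("V1_L", "V1_R")
  dimnames(a$data)[[2]] <- a$roi_ids
  res <- per_mouse_v1_similarity(a, a)
  expect_false(any(res$excluded))
  expect_equal(res$r, c(1, 1), tolerance = 1e-12)

  # a mouse with a 0.5% response in one condition is excluded
  weak <- mk(list(m1 = c(0.05, 0.05), m2 = c(0.005, 0.005)))
  weak$roi_ids <- c("V1_L", "V1_R")
  dimnames(weak$data)[[2]] <- weak$roi_ids
  res2 <- per_mouse_v1_similarity(a, weak)
  expect_true(res2$excluded[res2$mouse == "m2"])
  expect_match(res2$reason[res2$mouse == "m2"], "below threshold")
})

test_that("speed-activity correlation behaves on constructed sessions", {
  n <- 6000
  sp <- c(numeric(2000), rep(40, 2000), numeric(2000)) + runif(n)
  tr <- matrix(rep(sp, 2), ncol = 2, dimnames = list(NULL, c("V1_L", "M1_L")))
  s <- make_dff_session(tr, speed = sp)
  r <- speed_activity_correlation(s)
  expect_equal(r$r, c(1, 1), tolerance = 1e-12)

  set.seed(9)
  noise <- matrix(rnorm(n * 2), ncol = 2,
                  dimnames = list(NULL, c("V1_L", "M1_L")))
  rn <- speed_activity_correlation(make_dff_session(noise, speed = sp))
  expect_lt(max(abs(rn$r)), 0.1)

  still <- make_dff_session(noise, speed = numeric(n))
  expect_warning(rs <- speed_activity_correlation(still), "constant speed")
  expect_true(all(is.na(rs$r)))

  # session-to-mouse aggregation averages coefficients
  df <- rbind(r, within(r, {session <- "s02"; r <- r - 0.4}))
  agg <- aggregate_speed_activity(df)
  expect_equal(agg$r, c(0.8, 0.8), tolerance = 1e-12)
})

test_that("pairwise ROI correlations give 66 canonical rows with normalized
           distances", {
  geom <- default_roi_geometry()
  n <- 2000
  base <- sin(seq_len(n) / 20)
  tr <- matrix(rep(base, 12), ncol = 12, dimnames = list(NULL, geom$roi))
  s <- make_dff_session(tr)
  pc <- pairwise_roi_correlation(s, geom)
  expect_equal(nrow(pc), 66L)
  expect_equal(pc$r, rep(1, 66), tolerance = 1e-12)
  expect_true(all(pc$d_norm > 0))
  expect_true(all(match(pc$roi_a, geom$roi) < match(pc$roi_b, geom$roi)))

  # antiphase pair
  tr2 <- tr
  tr2[, "V1_R"] <- -base
  pc2 <- pairwise_roi_correlation(make_dff_session(tr2), geom)
  expect_equal(pc2$r[pc2$roi_a == "V1_L" & pc2$roi_b == "V1_R"], -1,
               tolerance = 1e-12)

  # zero-variance ROI flagged missing
  tr3 <- tr
  tr3[, "RSC_L"] <- 0
  pc3 <- pairwise_roi_correlation(make_dff_session(tr3), geom)
  expect_true(all(pc3$missing[pc3$roi_a == "RSC_L" | pc3$roi_b == "RSC_L"]))
  expect_true(all(is.na(pc3$r[pc3$missing])))

  # a bregma-lambda length pair normalizes to 1 by construction
  g2 <- default_roi_geometry(bregma_lambda_mm = 2)
  pd <- pair_distances(g2)
  expect_equal(pd$d_norm, pair_distances(default_roi_geometry())$d_norm * 2.1)
})

test_that("pairwise correlation matrix is symmetric PSD with unit diagonal", {
  set.seed(14)
  s <- preprocess_session(simulate_session("dark", "naive",
                                           tiny_cfg(session_duration_s = 120)),
                          window_s = 30)
  pc <- pairwise_roi_correlation(s)
  geom <- default_roi_geometry()
  C <- diag(12)
  idx <- cbind(match(pc$roi_a, geom$roi), match(pc$roi_b, geom$roi))
  C[idx] <- pc$r
  C[idx[, 2:1]] <- pc$r
  expect_equal(C, t(C))
  expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
})

test_that("density maps conserve mass and report the 50% contour", {
  set.seed(21)
  pairs <- make_pairs("m1", r = runif(500, -0.2, 0.95),
                      d_norm = runif(500, 0.05, 1.5),
                      roi_a = sprintf("a%d", 1:500),
                      roi_b = sprintf("b%d", 1:500))
  dm <- correlation_distance_density(pairs)
  expect_equal(sum(dm$grid), 500)
  expect_equal(sum(dm$smoothed), 500, tolerance = 1e-6)
  expect_equal(dm$contour_level, 0.5 * max(dm$smoothed))
  expect_equal(dim(dm$grid), c(40L, 40L))

  # N identical pairs: all mass in one bin before smoothing
  same <- make_pairs("m1", r = rep(0.5, 7), d_norm = rep(0.8, 7),
                     roi_a = sprintf("a%d", 1:7), roi_b = sprintf("b%d", 1:7))
  dm2 <- correlation_distance_density(same)
  expect_equal(max(dm2$grid), 7)
  expect_equal(sum(dm2$grid > 0), 1L)

  # invariance to pair ordering
  dm3 <- correlation_distance_density(pairs[sample(500), ])
  expect_equal(dm3$smoothed, dm$smoothed)
})

test_that("drug change normalizes per pair and splits at the 0.9 cutoff", {
  d <- c(0.3, 0.5, 0.9, 1.2)
  before <- make_pairs("m1", r = c(0.8, 0.6, 0.5, 0.4), d_norm = d,
                       roi_a = c("A", "B", "C", "D"),
                       roi_b = c("E", "F", "G", "H"))
  after <- before
  after$r <- c(0.8, 0.6, 0.25, 0.2)
  dc <- drug_change(before, after)
  expect_equal(dc$range, c("short", "short", "long", "long"))
  expect_equal(dc$change, c(0, 0, -0.5, -0.5))

  # boundary pair at exactly 0.9 is long-range
  expect_equal(dc$range[dc$d_norm == 0.9], "long")

  # session averaging happens before the change is formed
  before2 <- rbind(before, within(before, {session <- "s02"; r <- r + 0.2}))
  class(before2) <- class(before)
  dc2 <- drug_change(before2, after)
  expect_equal(dc2$change[dc2$roi_a == "C"], 0.25 / 0.6 - 1)

  # r_before == 0 pairs are dropped with a warning
  b0 <- make_pairs("m1", r = c(0, 0.5), d_norm = c(0.5, 1.0),
                   roi_a = c("A", "B"), roi_b = c("C", "D"))
  a0 <- b0; a0$r <- c(0.3, 0.4)
  expect_warning(dc3 <- drug_change(b0, a0), "dropped")
  expect_equal(nrow(dc3), 1L)

  sm <- summary(dc)
  expect_equal(sm["long", "median"], -0.5)
  expect_equal(sm["short", "n"], 2)
})
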