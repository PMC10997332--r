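test_that("onset detection matches the per-sample scan oracle", {
  cfg <- tiny_cfg(session_duration_s = 60)
  for (i in 1:20) {
    set.seed(200 + i)
    primary <- simulate_locomotion(60, cfg) + abs(rnorm(6000, sd = 0.2))
    other <- simulate_locomotion(60, cfg)
    got <- detect_onsets(primary, other, 100)
    want <- oracle_detect_onsets(primary, other, 100)
    expect_equal(as.data.frame(got), want)
  }
})

test_that("onset detection handles the documented edge cases", {
  fs <- 100
  expect_equal(nrow(detect_onsets(numeric(1000), numeric(1000), fs)), 0L)
  expect_error(detect_onsets(numeric(10), numeric(9), fs), "length")

  # single clean step 0 -> 40 at t = 5 s
  step <- c(numeric(500), rep(40, 200))
  ev <- detect_onsets(step, numeric(700), fs)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$valid)
  expect_equal(ev$time_s, 5)

  # second crossing 2 s after the first with running in between: invalid
  sp <- numeric(1200)
  sp[501:560] <- 40      # first bout at t = 5
  sp[561:700] <- 5       # still moving, below threshold
  sp[701:800] <- 40      # second crossing at t = 7
  ev2 <- detect_onsets(sp, numeric(1200), fs)
  expect_equal(nrow(ev2), 2L)
  expect_true(ev2$valid[1])
  expect_false(ev2$valid[2])
  expect_equal(ev2$exclusion_reason[2], "activity in pre-window")

  # crossing too early for a full exclusion window
  early <- c(numeric(100), rep(40, 100))
  ev3 <- detect_onsets(early, numeric(200), fs)
  expect_false(ev3$valid)
  expect_equal(ev3$exclusion_reason, "incomplete pre-window")

  # visual-flow onsets: activity in the OTHER (locomotion) trace vetoes
  flow <- c(numeric(500), rep(40, 200))
  loco <- c(rep(3, 450), numeric(250))
  ev4 <- detect_onsets(flow, loco, fs, type = "flow_open")
  expect_false(ev4$valid)
  expect_equal(ev4$type, "flow_open")
})

test_that("alignment window arithmetic and boundary drops are exact", {
  fs <- 100
  tr <- matrix(rep(seq_len(30000) / fs, 2), ncol = 2,
               dimnames = list(NULL, c("a", "b")))  # trace value = time
  ev <- structure(data.frame(time_s = c(100, 2, 299),
                             type = "loco_closed", valid = TRUE,
                             exclusion_reason = ""),
                  class = c("cf_events", "data.frame"))
  expect_message(al <- extract_aligned(tr, ev, fs), "2 event")
  expect_equal(dim(al$data), c(1, 2, 800))
  expect_equal(al$n_dropped, 2L)
  # snippet covers 95 s to 103 s
  expect_equal(unname(al$data[1, 1, 1]), 95 + 1 / fs)
  expect_equal(unname(al$data[1, 1, 800]), 103)

  cst <- matrix(2.5, 3000, 2, dimnames = list(NULL, c("a", "b")))
  ev1 <- structure(data.frame(time_s = 15, type = "loco_closed",
                              valid = TRUE, exclusion_reason = ""),
                   class = c("cf_events", "data.frame"))
  al2 <- extract_aligned(cst, ev1, fs)
  expect_true(all(al2$data == 2.5))
})

test_that("baseline subtraction uses the mode windows and is exact and
           idempotent", {
  modes <- list(stimulus = c(-0.2, 0), onset_gcamp = c(-2.9, -2.7),
                onset_egfp = c(-0.9, -0.7))
  set.seed(31)
  tr <- matrix(rnorm(30000 * 3), ncol = 3,
               dimnames = list(NULL, c("a", "b", "c")))
  ev <- structure(data.frame(time_s = c(50, 120, 200), type = "loco_closed",
                             valid = TRUE, exclusion_reason = ""),
                  class = c("cf_events", "data.frame"))
  al <- extract_aligned(tr, ev, 100)
  for (m in names(modes)) {
    b <- baseline_subtract(al, m)
    expect_identical(b$baseline_window_s, modes[[m]])
    bins <- corticoflow:::baseline_bins(b, modes[[m]])
    expect_equal(length(bins), round(diff(modes[[m]]) * 100))
    mu <- apply(b$data[, , bins, drop = FALSE], c(1, 2), mean)
    expect_lt(max(abs(mu)), 1e-13)
    # idempotent
    b2 <- baseline_subtract(b, m)
    expect_equal(b2$data, b$data, tolerance = 1e-13)
  }
  narrow <- extract_aligned(tr, ev, 100, window_s = c(-1, 1))
  expect_error(baseline_subtract(narrow, "onset_gcamp"), "onset_gcamp")
})

test_that("triggered averages pool onsets and bound them with bootstrap
           bands", {
  al <- make_aligned_constant(rep(2.5, 6), mice = rep(c("a", "b"), 3))
  tr <- triggered_average(al, n_boot = 200)
  expect_true(all(tr$mean == 2.5))
  expect_true(all(tr$ci_low == 2.5 & tr$ci_high == 2.5))  # zero variance
  expect_equal(tr$n_onsets, 6L)
  expect_equal(tr$n_mice, 2L)

  # two mice with constant responses 1 and 3: replicate means live on
  # {1, 2, 3} with probabilities {1/4, 1/2, 1/4}; the band stays inside
  al2 <- make_aligned_constant(c(1, 3), mice = c("a", "b"))
  set.seed(2)
  tr2 <- triggered_average(al2, n_boot = 4000)
  expect_true(all(tr2$ci_low >= 1 & tr2$ci_high <= 3))
  expect_equal(unname(tr2$mean[1, 1]), 2)
  hb <- hboot(c(1, 3), mouse = c("a", "b"), n_boot = 4000, keep_reps = TRUE)
  freqs <- table(factor(hb$reps, levels = c(1, 2, 3))) / 4000
  expect_equal(as.numeric(freqs), c(0.25, 0.5, 0.25), tolerance = 0.03)

  # invariance to onset order and mouse relabeling
  al3 <- make_aligned_constant(c(1, 1, 4, 4), mice = c("a", "a", "b", "b"))
  al3p <- make_aligned_constant(c(4, 4, 1, 1), mice = c("x", "x", "y", "y"))
  set.seed(5); t3 <- triggered_average(al3, n_boot = 500)
  set.seed(5); t3p <- triggered_average(al3p, n_boot = 500)
  expect_equal(t3$mean, t3p$mean)
  expect_equal(t3$ci_low, t3p$ci_low)

  expect_warning(triggered_average(make_aligned_constant(c(1, 2),
                                                         mice = c("a", "a")),
                                   n_boot = 100),
                 "single mouse")
})

test_that("bootstrap band covers the true mean at roughly the nominal rate", {
  set.seed(77)
  hits <- 0L
  n_sim <- 200L
  mice <- rep(letters[1:5], each = 4)
  for (i in seq_len(n_sim)) {
    vals <- rnorm(5, mean = 1)[match(mice, letters[1:5])] + rnorm(20)
    al <- make_aligned_constant(vals, mice = mice, window_s = c(-0.1, 0.1))
    tr <- triggered_average(al, n_boot = 400)
    hits <- hits + (tr$ci_low[1, 1] <= 1 && tr$ci_high[1, 1] >= 1)
  }
  expect_gt(hits / n_sim, 0.78)
  expect_lt(hits / n_sim, 0.97)
})

test_that("response maps localize to responsive pixels", {
  fs <- 100
  movie <- array(0, dim = c(3000, 4, 5))
  ev <- structure(data.frame(time_s = c(10, 20), type = "mismatch",
                             valid = TRUE, exclusion_reason = ""),
                  class = c("cf_events", "data.frame"))
  expect_equal(response_map(movie, ev, fs), matrix(0, 4, 5))
  # single bright pixel responding after each event
  for (t0 in c(10, 20))
    movie[(t0 * fs + 1):(t0 * fs + 50), 2, 3] <- 0.4
  m <- response_map(movie, ev, fs, avg_window_s = c(0, 1))
  expect_equal(m[2, 3], 0.4 * 50 / 100)
  expect_equal(sum(m != 0), 1L)
  expect_error(response_map(movie, ev[0, ], fs), "no usable events")
})

test_that("linear sum averages per mouse before summing", {
  a <- make_aligned_constant(c(1, 3), mice = c("m1", "m2"))
  b <- make_aligned_constant(c(2, 4), mice = c("m1", "m2"))
  ls1 <- linear_sum(a, b)
  expect_true(all(ls1$mean == 5))
  expect_true(all(abs(ls1$sem - 2) < 1e-12))
  # commutative
  ls2 <- linear_sum(b, a)
  expect_equal(ls1$mean, ls2$mean)
  # additive identity
  z <- make_aligned_constant(c(0, 0), mice = c("m1", "m2"))
  expect_true(all(linear_sum(a, z)$mean == 2))
  # mismatched mice
  c_ <- make_aligned_constant(c(1, 1), mice = c("m1", "m3"))
  expect_error(linear_sum(a, c_), "m3")
})
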