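test_that("locomotion generator is deterministic and respects bout config", {
  cfg <- tiny_cfg()
  set.seed(42)
  a <- simulate_locomotion(120, cfg)
  set.seed(42)
  b <- simulate_locomotion(120, cfg)
  expect_identical(a, b)
  expect_true(all(a >= 0))

  cfg0 <- tiny_cfg(bout_rate_hz = 0)
  expect_identical(as.numeric(simulate_locomotion(60, cfg0)),
                   numeric(6000))

  # one forced bout at t = 10 s, plateau 40 cm/s: a direct scan must find
  # exactly one upward 30 cm/s crossing near t = 10 s
  sp <- simulate_locomotion(60, cfg0,
                            bouts = data.frame(start_s = 10, duration_s = 5,
                                               peak_cms = 40))
  cross <- which(sp[-1] >= 30 & sp[-length(sp)] < 30) + 1L
  expect_length(cross, 1L)
  expect_lt(abs((cross - 1) / 100 - 10), 1)

  # ramps are continuous: no jump beyond the configured max acceleration
  expect_lt(max(abs(diff(sp))) * 100, cfg0$max_accel_cms2)
})

test_that("invalid configuration names the offending field", {
  expect_error(sim_config(fs_hz = -1), "fs_hz")
  expect_error(sim_config(drug_longrange_scale = 1.5), "drug_longrange_scale")
  expect_error(sim_config(session_duration_s = 10.005), "session_duration_s")
  expect_error(simulate_session("weird", "naive", tiny_cfg()),
               "unknown condition")
  expect_error(simulate_session("dark", "mystery", tiny_cfg()),
               "unknown treatment")
})

test_that("closed loop couples flow to locomotion exactly when undisturbed", {
  cfg <- tiny_cfg(mismatch_rate_hz = 0, noise_sd = 0, drift_slope = 0,
                  coupling_gain = 1.5)
  set.seed(7)
  s <- simulate_session("closed", "naive", cfg)
  expect_identical(s$flow, 1.5 * s$speed)

  set.seed(7)
  sd_ <- simulate_session("dark", "naive", cfg)
  expect_identical(sd_$flow, numeric(length(sd_$speed)))
})

test_that("open-loop flow is statistically independent of own locomotion", {
  cfg <- tiny_cfg(session_duration_s = 300)
  rs <- vapply(1:30, function(i) {
    set.seed(100 + i)
    s <- simulate_session("open", "naive", cfg)
    if (sd(s$speed) == 0 || sd(s$flow) == 0) return(0)
    cor(s$speed, s$flow)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
  expect_lt(max(abs(rs)), 0.6)
})

test_that("grating sessions record onsets with the configured timing", {
  set.seed(5)
  s <- simulate_session("grating", "naive", tiny_cfg(session_duration_s = 300))
  ev <- s$events
  expect_true(all(ev$type == "grating"))
  expect_gt(nrow(ev), 10)
  expect_true(all(diff(ev$time_s) > 0))
  expect_true(mean(ev$duration_s) > 3 && mean(ev$duration_s) < 9)
})

test_that("zero long-range coupling removes cross-group latent correlation", {
  cfg <- tiny_cfg(n_latents = 0L, drug_longrange_scale = 0)
  mod <- model_roi_correlation(cfg, treatment = "drug")
  g <- default_roi_geometry()
  cross <- outer(g$group, g$group, "!=")
  expect_equal(max(abs(mod[cross])), 0)
  expect_equal(unname(mod[1, 1]), 1)

  # and the sample covariance follows: noise-free drive-free short session
  cfg2 <- sim_config(noise_sd = 0, drift_slope = 0, bout_rate_hz = 0,
                     n_latents = 0L, drug_longrange_scale = 0,
                     session_duration_s = 300)
  set.seed(3)
  s <- simulate_session("dark", "drug", cfg2)
  emp <- cor(s$traces)
  expect_lt(max(abs(emp[cross])), 0.1)
})

test_that("sample correlation of a long noise-free session converges to the
           latent-model correlation", {
  cfg <- sim_config(noise_sd = 0, drift_slope = 0, bout_rate_hz = 0,
                    session_duration_s = 900)
  set.seed(11)
  s <- simulate_session("dark", "naive", cfg)
  expect_lt(max(abs(cor(s$traces) - model_roi_correlation(cfg))), 0.05)

  set.seed(12)
  cfgd <- sim_config(noise_sd = 0, drift_slope = 0, bout_rate_hz = 0,
                     session_duration_s = 900, drug_longrange_scale = 0.5)
  sdrug <- simulate_session("dark", "drug", cfgd)
  expect_lt(max(abs(cor(sdrug$traces) -
                    model_roi_correlation(cfgd, treatment = "drug"))), 0.05)
})

test_that("cohorts are reproducible and carry complete ground truth", {
  cfg <- sim_config(n_mice = 2, sessions_per_condition = 1,
                    session_duration_s = 60,
                    conditions = c("closed", "dark"), seed = 21)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$sessions[[1]]$traces, b$sessions[[1]]$traces)
  expect_identical(a$truth, b$truth)

  expect_setequal(unique(a$truth$treatment_scale_applied$treatment),
                  c("naive", "drug"))
  expect_true(all(a$truth$treatment_scale_applied$longrange_coupling[
    a$truth$treatment_scale_applied$treatment == "drug"] ==
      cfg$drug_longrange_scale))

  # every detectable onset is explainable by an injected bout: each
  # threshold crossing lies within a recorded bout window
  for (sid in names(a$sessions)) {
    s <- a$sessions[[sid]]
    tr <- a$truth$true_onsets
    bouts <- tr[tr$session == sid & tr$type == "bout", ]
    cross <- which(s$speed[-1] >= 30 & s$speed[-length(s$speed)] < 30) + 1L
    for (i in cross) {
      t <- (i - 1) / cfg$fs_hz
      expect_true(any(t >= bouts$time_s & t <= bouts$time_s + 30))
    }
  }
})

test_that("artifact injection matches its contract", {
  s <- zero_session(n = 30000)
  s$meta$units <- "dff"

  expect_identical(inject_artifacts(s, data.frame(kind = character(0),
                                                  start_s = numeric(0),
                                                  end_s = numeric(0),
                                                  level = numeric(0))),
                   s)
  expect_error(inject_artifacts(s, data.frame(kind = "seizure", start_s = 290,
                                              end_s = 310, level = 0.35)),
               "bounds")

  sz <- inject_artifacts(s, data.frame(kind = "seizure", start_s = 100,
                                       end_s = 112, level = 0.35))
  m <- rowMeans(sz$traces)
  expect_true(all(m[10002:11200] >= 0.35))
  expect_true(all(m[1:9999] == 0))

  expect_warning(
    inject_artifacts(s, data.frame(kind = "seizure",
                                   start_s = c(100, 105),
                                   end_s = c(110, 115),
                                   level = 0.35)),
    "merged")

  dip <- inject_artifacts(s, data.frame(kind = "hemodip", start_s = 100,
                                        end_s = 110, level = 0.1))
  expect_lt(min(dip$traces), -0.09)
  dr <- inject_artifacts(s, data.frame(kind = "drift", start_s = 100,
                                       end_s = 200, level = 0.05))
  expect_equal(unname(dr$traces[30000, 1]), 0.05, tolerance = 1e-6)
})
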