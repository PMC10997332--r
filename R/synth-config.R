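#' Simulation configuration for synthetic cohorts
#'
#' Builds and validates the parameter set that defines a synthetic cohort of
#' mice and recording sessions. Defaults mirror the study conditions the
#' analysis is designed for: 100 Hz sampling, 5-minute sessions, locomotion in
#' well-separated bouts that cross the 30 cm/s onset threshold, closed-loop
#' visual flow coupled to locomotion with 1-s mismatch halts, and ROI activity
#' built from behavioral drives plus spatially structured latent factors that
#' give distance-dependent inter-areal correlations.
#'
#' @param n_mice Number of mice in the cohort.
#' @param sessions_per_condition Recording sessions per condition (and per
#'   treatment) for each mouse.
#' @param conditions Conditions simulated per mouse; subset of
#'   `"closed"`, `"open"`, `"dark"`, `"grating"`.
#' @param fs_hz Sampling rate in Hz.
#' @param session_duration_s Session duration in seconds; `fs_hz *
#'   session_duration_s` must be a whole sample count.
#' @param bout_rate_hz Rate (1/s) at which locomotion bouts are initiated from
#'   quiescence. `0` produces a fully quiescent trace.
#' @param bout_duration_s Mean bout duration in seconds.
#' @param bout_speed_cms Mean plateau running speed in cm/s. Must exceed the
#'   30 cm/s detection threshold for onsets to be found downstream.
#' @param ramp_s Duration of the raised-cosine deceleration out of a bout, in
#'   seconds. The kick-off into a bout is ballistic: a raised-cosine ramp at
#'   the acceleration limit, lasting tens of milliseconds, so a 30 cm/s
#'   crossing is not preceded by slow sub-threshold creep that the strict
#'   pre-onset quiescence rule would veto.
#' @param max_accel_cms2 Maximum allowed acceleration (cm/s^2); ramps never
#'   exceed it sample-to-sample.
#' @param coupling_gain Dimensionless gain from locomotion speed to visual
#'   flow speed in the closed-loop condition.
#' @param mismatch_rate_hz Rate (1/s) of 1-s visual-flow halts injected into
#'   closed-loop sessions.
#' @param n_latents Number of short-range latent factors (anchored at ROI
#'   centers; 0 disables them).
#' @param loading_length_scale_mm Spatial decay scale (mm) of the short-range
#'   latent loadings, `exp(-d / scale)`.
#' @param latent_tau_s Autocorrelation time constant of the latent factors in
#'   seconds.
#' @param calcium_tau_s Decay time constant of the single-exponential calcium
#'   indicator kernel in seconds.
#' @param drug_longrange_scale Factor in \[0, 1\] applied to the coupling of
#'   the long-range (anterior-posterior) latent under `"drug"` treatment; the
#'   model correlation between anterior and posterior latent components equals
#'   this factor, so long-range covariance scales linearly with it.
#' @param noise_sd White-noise standard deviation in dF/F fraction.
#' @param drift_slope Slow linear fluorescence drift in dF/F fraction per
#'   minute (emulating thermal brightening of the LED).
#' @param dff_scale Overall response amplitude in dF/F fraction applied to the
#'   summed, kernel-convolved drives.
#' @param baseline_f0 Baseline raw fluorescence level (arbitrary camera
#'   units); sessions store raw fluorescence `f0 * (1 + dff)`.
#' @param phenotype Area-weight preset: `"l5it"` (posterior visual drive
#'   opposes locomotion drive in closed loop, as for layer-5 IT populations)
#'   or `"broad"` (uniformly positive, as for brain-wide expression).
#' @param mismatch_amp Amplitude scale of the mismatch response drive.
#' @param replay_from_session If `TRUE`, open-loop visual flow replays the
#'   locomotion of the paired closed-loop session of the same mouse; if
#'   `FALSE` (default) it replays an independent locomotion draw.
#' @param seed RNG seed used by [simulate_cohort()]; `NULL` leaves the RNG
#'   state untouched.
#'
#' @return A validated list of class `cf_simconfig`.
#' @export
sim_config <- function(n_mice = 5L,
                       sessions_per_condition = 2L,
                       conditions = c("closed", "open", "dark", "grating"),
                       fs_hz = 100,
                       session_duration_s = 300,
                       bout_rate_hz = 0.02,
                       bout_duration_s = 5,
                       bout_speed_cms = 40,
                       ramp_s = 0.5,
                       max_accel_cms2 = 5000,
                       coupling_gain = 1,
                       mismatch_rate_hz = 0.02,
                       n_latents = 12L,
                       loading_length_scale_mm = 1.2,
                       latent_tau_s = 0.2,
                       calcium_tau_s = 0.5,
                       drug_longrange_scale = 0.5,
                       noise_sd = 0.01,
                       drift_slope = 0.01,
                       dff_scale = 0.05,
                       baseline_f0 = 1000,
                       phenotype = c("l5it", "broad"),
                       mismatch_amp = 1,
                       replay_from_session = FALSE,
                       seed = NULL) {
  phenotype <- match.arg(phenotype)
  cfg <- list(
    n_mice = n_mice, sessions_per_condition = sessions_per_condition,
    conditions = conditions, fs_hz = fs_hz,
    session_duration_s = session_duration_s, bout_rate_hz = bout_rate_hz,
    bout_duration_s = bout_duration_s, bout_speed_cms = bout_speed_cms,
    ramp_s = ramp_s, max_accel_cms2 = max_accel_cms2,
    coupling_gain = coupling_gain, mismatch_rate_hz = mismatch_rate_hz,
    n_latents = n_latents,
    loading_length_scale_mm = loading_length_scale_mm,
    latent_tau_s = latent_tau_s, calcium_tau_s = calcium_tau_s,
    drug_longrange_scale = drug_longrange_scale, noise_sd = noise_sd,
    drift_slope = drift_slope, dff_scale = dff_scale,
    baseline_f0 = baseline_f0, phenotype = phenotype,
    mismatch_amp = mismatch_amp,
    replay_from_session = replay_from_session, seed = seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "cf_simconfig"
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid configuration: field '", field, "' ", why, call. = FALSE)
  }
  scalar_pos <- c("fs_hz", "session_duration_s", "bout_duration_s",
                  "bout_speed_cms", "ramp_s", "max_accel_cms2",
                  "coupling_gain", "latent_tau_s", "calcium_tau_s",
                  "dff_scale", "baseline_f0", "loading_length_scale_mm",
                  "mismatch_amp")
  for (f in scalar_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      bad(f, "must be a positive finite number")
  }
  scalar_nonneg <- c("bout_rate_hz", "mismatch_rate_hz", "noise_sd",
                     "drift_slope")
  for (f in scalar_nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      bad(f, "must be a nonnegative finite number")
  }
  for (f in c("n_mice", "sessions_per_condition")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      bad(f, "must be a positive whole number")
  }
  if (!is.numeric(cfg$n_latents) || length(cfg$n_latents) != 1L ||
      cfg$n_latents < 0 || cfg$n_latents != round(cfg$n_latents))
    bad("n_latents", "must be a nonnegative whole number")
  s <- cfg$drug_longrange_scale
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s < 0 || s > 1)
    bad("drug_longrange_scale", "must lie in [0, 1]")
  n <- cfg$fs_hz * cfg$session_duration_s
  if (abs(n - round(n)) > 1e-8)
    bad("session_duration_s", "must give a whole sample count at fs_hz")
  if (!all(cfg$conditions %in% c("closed", "open", "dark", "grating")))
    bad("conditions", "contains an unknown condition label")
  invisible(cfg)
}

# Per-area drive weights, expanded to the 12 ROIs in geometry order.
area_weights <- function(phenotype, geometry) {
  areas <- c("V1", "V2am", "RSC", "M1", "A24b", "M2")
  loco <- c(V1 = 0.4, V2am = 0.4, RSC = 0.5, M1 = 0.7, A24b = 0.6, M2 = 0.7)
  if (phenotype == "l5it") {
    vis <- c(V1 = -1.0, V2am = -0.7, RSC = -0.4, M1 = 0, A24b = 0, M2 = 0)
    mm <- c(V1 = 1.0, V2am = 0.6, RSC = 0, M1 = 0, A24b = 0, M2 = 0)
  } else {
    vis <- c(V1 = 0.5, V2am = 0.4, RSC = 0.3, M1 = 0.1, A24b = 0.1, M2 = 0.1)
    mm <- c(V1 = 0.8, V2am = 0.5, RSC = 0.2, M1 = 0, A24b = 0, M2 = 0)
  }
  stopifnot(all(geometry$area %in% areas))
  list(loco = unname(loco[geometry$area]),
       visual = unname(vis[geometry$area]),
       mismatch = unname(mm[geometry$area]))
}

#' Short-range latent loadings implied by a configuration
#'
#' Loadings of the `n_latents` short-range latent factors on the 12 ROIs.
#' Factor `k` is anchored at the center of ROI `k` (anchors cycle through the
#' geometry if `n_latents < 12`) and loads ROI `i` as
#' `exp(-d(i, anchor_k) / loading_length_scale_mm)`.
#'
#' @param cfg A `cf_simconfig`.
#' @param geometry A `cf_geometry`.
#' @return ROI x latent numeric matrix (possibly zero columns).
#' @export
latent_loadings <- function(cfg, geometry = default_roi_geometry()) {
  nr <- nrow(geometry)
  k <- cfg$n_latents
  if (k == 0L) {
    return(matrix(0, nrow = nr, ncol = 0L,
                  dimnames = list(geometry$roi, NULL)))
  }
  anchors <- ((seq_len(k) - 1L) %% nr) + 1L
  d <- sqrt(outer(geometry$x_mm, geometry$x_mm[anchors], "-")^2 +
            outer(geometry$y_mm, geometry$y_mm[anchors], "-")^2)
  B <- exp(-d / cfg$loading_length_scale_mm)
  dimnames(B) <- list(geometry$roi, paste0("latent", seq_len(k)))
  B
}

#' Model-implied ROI correlation matrix of the latent structure
#'
#' Stationary correlation matrix of the latent part of the generative model
#' (short-range anchored factors plus the anterior-posterior long-range
#' factor), i.e. the correlation a drive-free, noise-free session converges
#' to. Under `"drug"` treatment the anterior-posterior block of the long-range
#' factor is multiplied by `drug_longrange_scale`.
#'
#' @inheritParams latent_loadings
#' @param treatment `"naive"`, `"saline"` or `"drug"`.
#' @return 12 x 12 correlation matrix.
#' @export
model_roi_correlation <- function(cfg, geometry = default_roi_geometry(),
                                  treatment = c("naive", "saline", "drug")) {
  treatment <- match.arg(treatment)
  rho <- if (treatment == "drug") cfg$drug_longrange_scale else 1
  B <- latent_loadings(cfg, geometry)
  G <- matrix(rho, nrow(geometry), nrow(geometry))
  same <- outer(geometry$group, geometry$group, "==")
  G[same] <- 1
  sigma <- G + B %*% t(B)
  dimnames(sigma) <- list(geometry$roi, geometry$roi)
  stats::cov2cor(sigma)
}
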