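# Unit-variance AR(1) series with time constant tau_s.
ar1_series <- function(n, tau_s, fs_hz) {
  phi <- exp(-1 / (fs_hz * tau_s))
  innov <- rnorm(n) * sqrt(1 - phi^2)
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = rnorm(1L)))
}

# Convolution with a single-exponential calcium kernel (decay tau_s),
# normalized to unit area, implemented as a recursive filter.
calcium_filter <- function(x, tau_s, fs_hz) {
  alpha <- exp(-1 / (fs_hz * tau_s))
  (1 - alpha) * as.numeric(stats::filter(x, alpha, method = "recursive"))
}

new_session <- function(traces, speed, flow, events, meta) {
  structure(list(traces = traces, speed = speed, flow = flow,
                 events = events, meta = meta),
            class = "cf_session")
}

#' @export
print.cf_session <- function(x, ...) {
  cat(sprintf("<cf_session %s: %s/%s, %d ROIs x %d samples @ %g Hz, %s>\n",
              x$meta$session_id, x$meta$condition, x$meta$treatment,
              ncol(x$traces), nrow(x$traces), x$meta$fs_hz, x$meta$units))
  invisible(x)
}

#' Simulate one recording session
#'
#' Generates a 5-minute (by default) session of one mouse in one condition:
#' locomotion speed, visual-flow speed, stimulus events, and raw fluorescence
#' traces for the 12 ROIs. ROI activity is a weighted sum of a locomotion
#' drive, a visual-flow drive, a mismatch-response drive, the
#' anterior-posterior long-range latent, and the short-range spatial latents;
#' the sum is convolved with the calcium kernel, scaled to dF/F units, and
#' embedded in raw fluorescence `baseline_f0 * (1 + dff + drift + noise)`.
#'
#' Conditions: `"closed"` couples flow to locomotion (`coupling_gain`) except
#' during injected 1-s mismatch halts where flow is zero; `"open"` replays an
#' independent locomotion draw (or `replay_speed`); `"dark"` has zero flow;
#' `"grating"` has zero flow plus drifting-grating blocks (6 +/- 2 s duration,
#' 4.5 +/- 1.5 s gray intervals) that drive the visual weights.
#'
#' Under `treatment = "drug"` the correlation between the anterior and
#' posterior streams of the long-range latent is set to
#' `drug_longrange_scale`, so model covariance between the two groups scales
#' linearly with that factor while ROI variances are unchanged.
#'
#' @param condition One of `"closed"`, `"open"`, `"dark"`, `"grating"`.
#' @param treatment One of `"naive"`, `"drug"`, `"saline"`.
#' @param cfg A `cf_simconfig`.
#' @param geometry A `cf_geometry`.
#' @param mouse_id,session_id Labels stored in the session metadata.
#' @param replay_speed Optional speed trace whose scaled copy is replayed as
#'   open-loop flow (used when `replay_from_session` is set).
#' @return A `cf_session` with raw-fluorescence traces (`meta$units ==
#'   "raw"`), behavior traces, an event table, and a `"truth"` attribute
#'   recording injected bouts, events and the applied long-range coupling.
#' @export
simulate_session <- function(condition, treatment, cfg,
                             geometry = default_roi_geometry(),
                             mouse_id = "m01", session_id = "s01",
                             replay_speed = NULL) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% c("closed", "open", "dark", "grating"))
    stop("unknown condition label: ", paste(condition, collapse = ", "),
         call. = FALSE)
  if (!is.character(treatment) || length(treatment) != 1L ||
      !treatment %in% c("naive", "drug", "saline"))
    stop("unknown treatment label: ", paste(treatment, collapse = ", "),
         call. = FALSE)
  validate_sim_config(cfg)
  fs <- cfg$fs_hz
  dur <- cfg$session_duration_s
  n <- round(fs * dur)
  dt <- 1 / fs

  speed <- simulate_locomotion(dur, cfg)
  events <- data.frame(time_s = numeric(0), type = character(0),
                       duration_s = numeric(0), stringsAsFactors = FALSE)

  flow <- numeric(n)
  if (condition == "closed") {
    flow <- cfg$coupling_gain * speed
    if (cfg$mismatch_rate_hz > 0) {
      n_mm <- rpois(1L, cfg$mismatch_rate_hz * dur)
      if (n_mm > 0) {
        tm <- sort(runif(n_mm, min = 1, max = max(1, dur - 2)))
        # keep halts separated by at least their own 1 s duration
        keep <- c(TRUE, diff(tm) > 1)
        tm <- tm[keep]
        for (t0 in tm) {
          idx <- seq(round(t0 * fs) + 1L, min(n, round((t0 + 1) * fs)))
          flow[idx] <- 0
        }
        events <- rbind(events, data.frame(time_s = tm, type = "mismatch",
                                           duration_s = 1))
      }
    }
  } else if (condition == "open") {
    if (is.null(replay_speed)) replay_speed <- simulate_locomotion(dur, cfg)
    flow <- cfg$coupling_gain * as.numeric(replay_speed)
  } else if (condition == "grating") {
    t <- runif(1L, 2, 4)
    while (t < dur) {
      g_dur <- max(0.5, rnorm(1L, 6, 2))
      events <- rbind(events, data.frame(time_s = t, type = "grating",
                                         duration_s = g_dur))
      t <- t + g_dur + max(0.5, rnorm(1L, 4.5, 1.5))
    }
  }

  w <- area_weights(cfg$phenotype, geometry)
  B <- latent_loadings(cfg, geometry)
  rho <- if (treatment == "drug") cfg$drug_longrange_scale else 1

  loco_n <- speed / cfg$bout_speed_cms
  flow_n <- flow / (cfg$coupling_gain * cfg$bout_speed_cms)

  mm_drive <- numeric(n)
  grat_drive <- numeric(n)
  for (r in seq_len(nrow(events))) {
    idx <- seq(round(events$time_s[r] * fs) + 1L,
               min(n, round((events$time_s[r] + events$duration_s[r]) * fs)))
    if (events$type[r] == "mismatch") {
      # mismatch is a prediction error: effective only while locomoting
      mm_drive[idx] <- cfg$mismatch_amp * loco_n[idx]
    } else if (events$type[r] == "grating") {
      grat_drive[idx] <- 1
    }
  }

  n_roi <- nrow(geometry)
  drive <- outer(loco_n, w$loco) + outer(flow_n, w$visual) +
    outer(mm_drive, w$mismatch) + outer(grat_drive, w$visual)

  if (ncol(B) > 0) {
    S <- vapply(seq_len(ncol(B)),
                function(k) ar1_series(n, cfg$latent_tau_s, fs),
                numeric(n))
    drive <- drive + S %*% t(B)
  }
  z_core <- ar1_series(n, cfg$latent_tau_s, fs)
  z_post <- if (rho < 1) {
    rho * z_core + sqrt(1 - rho^2) * ar1_series(n, cfg$latent_tau_s, fs)
  } else z_core
  long <- cbind(z_core, z_post)[, match(geometry$group,
                                        c("anterior", "posterior"))]
  drive <- drive + long

  traces <- apply(drive, 2L, calcium_filter, tau_s = cfg$calcium_tau_s,
                  fs_hz = fs)
  dff <- cfg$dff_scale * traces
  drift <- cfg$drift_slope * (seq_len(n) - 1L) * dt / 60
  if (cfg$noise_sd > 0)
    dff <- dff + matrix(rnorm(n * n_roi, sd = cfg$noise_sd), n, n_roi)
  raw <- cfg$baseline_f0 * (1 + sweep(dff, 1L, drift, "+"))
  colnames(raw) <- geometry$roi

  meta <- list(mouse_id = mouse_id, session_id = session_id,
               genotype = cfg$phenotype, condition = condition,
               treatment = treatment, fs_hz = fs, indicator = "gcamp",
               units = "raw",
               bregma_lambda_mm = attr(geometry, "bregma_lambda_mm"),
               schema_version = "1.0")
  sess <- new_session(raw, as.vector(speed), as.vector(flow), events, meta)
  attr(sess, "truth") <- list(bouts = attr(speed, "bouts"), events = events,
                              longrange_coupling = rho)
  sess
}

#' Simulate a full cohort with ground truth
#'
#' Generates `n_mice` mice, each with `sessions_per_condition` sessions per
#' condition and per treatment, sharing one latent-loading structure. When
#' `replay_from_session` is set in the config, each open-loop session replays
#' the locomotion of the matching closed-loop session of the same mouse and
#' treatment.
#'
#' @param cfg A `cf_simconfig`; `cfg$seed` (if non-`NULL`) seeds the RNG so
#'   identical configs give identical cohorts.
#' @param treatments Treatment labels simulated per mouse, in order.
#' @param geometry A `cf_geometry` shared by the cohort.
#' @return A list of class `cf_cohort` with elements `sessions` (list of
#'   `cf_session`), `truth` (injected onsets/events per session, latent
#'   loadings, applied long-range coupling per session, artifact windows) and
#'   `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_mice = 2, sessions_per_condition = 1,
#'                                   session_duration_s = 60, seed = 7))
#' length(coh$sessions)
simulate_cohort <- function(cfg, treatments = c("naive", "drug"),
                            geometry = default_roi_geometry()) {
  validate_sim_config(cfg)
  stopifnot(all(treatments %in% c("naive", "drug", "saline")))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  sessions <- list()
  truth_onsets <- list()
  scale_rows <- list()
  for (m in seq_len(cfg$n_mice)) {
    mouse <- sprintf("m%02d", m)
    for (trt in treatments) {
      closed_speeds <- list()
      for (cond in cfg$conditions) {
        for (k in seq_len(cfg$sessions_per_condition)) {
          sid <- sprintf("%s_%s_%s_%02d", mouse, trt, cond, k)
          replay <- NULL
          if (cond == "open" && isTRUE(cfg$replay_from_session) &&
              length(closed_speeds) >= k)
            replay <- closed_speeds[[k]]
          sess <- simulate_session(cond, trt, cfg, geometry,
                                   mouse_id = mouse, session_id = sid,
                                   replay_speed = replay)
          if (cond == "closed") closed_speeds[[k]] <- sess$speed
          tr <- attr(sess, "truth")
          bout_df <- tr$bouts
          ev_df <- tr$events
          ons <- rbind(
            if (nrow(bout_df))
              data.frame(mouse = mouse, session = sid,
                         time_s = bout_df$start_s, type = "bout"),
            if (nrow(ev_df))
              data.frame(mouse = mouse, session = sid,
                         time_s = ev_df$time_s, type = ev_df$type)
          )
          truth_onsets[[sid]] <- ons
          scale_rows[[sid]] <- data.frame(mouse = mouse, session = sid,
                                          treatment = trt,
                                          longrange_coupling =
                                            tr$longrange_coupling)
          sessions[[sid]] <- sess
        }
      }
    }
  }
  truth <- list(
    true_onsets = do.call(rbind, unname(truth_onsets)),
    latent_loadings = latent_loadings(cfg, geometry),
    treatment_scale_applied = do.call(rbind, unname(scale_rows)),
    artifact_windows = data.frame(session = character(0),
                                  start_s = numeric(0), end_s = numeric(0),
                                  kind = character(0))
  )
  structure(list(sessions = sessions, truth = truth, config = cfg,
                 geometry = geometry),
            class = "cf_cohort")
}
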