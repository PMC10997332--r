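#' Simulate a bout-structured locomotion speed trace
#'
#' Two-state (quiescent/bout) semi-Markov model of treadmill running: the
#' animal sits at 0 cm/s, initiates bouts at rate `bout_rate_hz`, kicks the
#' ball to the plateau speed with a ballistic raised-cosine ramp at the
#' acceleration limit (tens of milliseconds, so the onset-threshold crossing
#' is not preceded by a long sub-threshold creep), and decelerates smoothly
#' over `ramp_s`. Quiescent gaps are exponential, bout durations gamma
#' distributed (shape 4, mean `bout_duration_s`), plateau speeds normal
#' around `bout_speed_cms`. No sample-to-sample acceleration exceeds
#' `max_accel_cms2`.
#'
#' Consumes the current RNG stream; seed it (or use [simulate_cohort()], which
#' seeds from its config) for reproducibility.
#'
#' @param duration_s Trace duration in seconds (> 0).
#' @param cfg A `cf_simconfig`, see [sim_config()].
#' @param bouts Optional `data.frame(start_s, duration_s, peak_cms)` forcing
#'   an exact deterministic bout schedule instead of the random one.
#' @return Numeric speed vector (cm/s) of length `duration_s * fs_hz`, with a
#'   `data.frame` of the realized bouts in attribute `"bouts"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' set.seed(1)
#' speed <- simulate_locomotion(60, cfg)
simulate_locomotion <- function(duration_s, cfg, bouts = NULL) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("invalid configuration: field 'duration_s' must be positive",
         call. = FALSE)
  validate_sim_config(cfg)
  fs <- cfg$fs_hz
  n <- round(duration_s * fs)
  speed <- numeric(n)

  if (is.null(bouts)) {
    bouts <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                        peak_cms = numeric(0))
    if (cfg$bout_rate_hz > 0) {
      t <- 0
      while (TRUE) {
        gap <- rexp(1L, rate = cfg$bout_rate_hz)
        start <- t + gap
        if (start >= duration_s) break
        dur <- max(1, rgamma(1L, shape = 4, rate = 4 / cfg$bout_duration_s))
        peak <- rnorm(1L, cfg$bout_speed_cms, 0.15 * cfg$bout_speed_cms)
        peak <- min(max(peak, 0.5 * cfg$bout_speed_cms),
                    1.5 * cfg$bout_speed_cms)
        bouts <- rbind(bouts, data.frame(start_s = start, duration_s = dur,
                                         peak_cms = peak))
        t <- start + dur
      }
    }
  } else {
    stopifnot(all(c("start_s", "duration_s", "peak_cms") %in% names(bouts)))
  }

  dt <- 1 / fs
  for (b in seq_len(nrow(bouts))) {
    start <- bouts$start_s[b]
    dur <- bouts$duration_s[b]
    peak <- bouts$peak_cms[b]
    # raised-cosine ramps; peak slope pi*peak/(2*ramp) respects max accel.
    # The up-ramp runs at the acceleration limit (ballistic kick-off);
    # the down-ramp takes ramp_s.
    ramp_up <- min(pi * peak / (2 * cfg$max_accel_cms2), dur / 2)
    ramp_dn <- min(max(cfg$ramp_s, pi * peak / (2 * cfg$max_accel_cms2)),
                   dur / 2)
    i0 <- round(start * fs) + 1L
    i1 <- min(n, round((start + dur) * fs))
    if (i0 > n || i1 < i0) next
    tt <- (seq(i0, i1) - i0) * dt
    prof <- rep(peak, length(tt))
    up <- tt < ramp_up
    prof[up] <- peak * (1 - cos(pi * tt[up] / ramp_up)) / 2
    down <- tt > dur - ramp_dn
    prof[down] <- peak * (1 - cos(pi * (dur - tt[down]) / ramp_dn)) / 2
    seg <- seq(i0, i1)
    speed[seg] <- pmax(speed[seg], pmax(prof, 0))
  }
  attr(speed, "bouts") <- bouts
  speed
}
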