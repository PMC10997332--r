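#' Inject acquisition artifacts into a session
#'
#' Adds controlled artifacts to the raw traces of a session so downstream
#' quality control can be exercised against known ground truth:
#'
#' * `"seizure"`: raises all ROI traces to at least `level` dF/F above
#'   baseline for the window (a floor, so the across-ROI mean stays above the
#'   stated level for the stated duration). Overlapping seizure windows are
#'   merged with a warning.
#' * `"drift"`: adds a slow linear ramp reaching `level` dF/F at the window
#'   end and persisting afterwards.
#' * `"hemodip"`: subtracts a transient Gaussian-shaped dip of depth `level`
#'   centered in the window (hemodynamic occlusion).
#'
#' @param session A `cf_session` with raw traces (`meta$units == "raw"`).
#' @param artifacts `data.frame(kind, start_s, end_s, level)`; `kind` in
#'   `"seizure"`, `"drift"`, `"hemodip"`; `level` in dF/F fraction.
#' @return The modified session; applied windows are appended to the session
#'   attribute `"artifacts"`. An empty `artifacts` table returns the session
#'   unchanged.
#' @export
inject_artifacts <- function(session, artifacts) {
  stopifnot(inherits(session, "cf_session"))
  need <- c("kind", "start_s", "end_s", "level")
  if (!all(need %in% names(artifacts)))
    stop("artifacts must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(artifacts) == 0L) return(session)
  fs <- session$meta$fs_hz
  n <- nrow(session$traces)
  dur <- n / fs
  if (any(artifacts$start_s < 0) || any(artifacts$end_s > dur) ||
      any(artifacts$end_s <= artifacts$start_s))
    stop("artifact window outside session bounds", call. = FALSE)
  if (!all(artifacts$kind %in% c("seizure", "drift", "hemodip")))
    stop("unknown artifact kind", call. = FALSE)

  # merge overlapping seizure windows
  sz <- artifacts[artifacts$kind == "seizure", , drop = FALSE]
  if (nrow(sz) > 1L) {
    sz <- sz[order(sz$start_s), , drop = FALSE]
    merged <- sz[1, , drop = FALSE]
    overlapped <- FALSE
    for (i in seq_len(nrow(sz))[-1]) {
      j <- nrow(merged)
      if (sz$start_s[i] <= merged$end_s[j]) {
        merged$end_s[j] <- max(merged$end_s[j], sz$end_s[i])
        merged$level[j] <- max(merged$level[j], sz$level[i])
        overlapped <- TRUE
      } else merged <- rbind(merged, sz[i, , drop = FALSE])
    }
    if (overlapped)
      warning("overlapping seizure windows merged", call. = FALSE)
    artifacts <- rbind(merged,
                       artifacts[artifacts$kind != "seizure", , drop = FALSE])
  }

  f0 <- if (!is.null(session$meta$units) && session$meta$units == "raw") {
    apply(session$traces, 2L, median)
  } else rep(1, ncol(session$traces))  # dF/F traces: levels add directly

  for (i in seq_len(nrow(artifacts))) {
    a <- artifacts[i, ]
    idx <- seq(round(a$start_s * fs) + 1L, min(n, round(a$end_s * fs)))
    if (a$kind == "seizure") {
      floor_vals <- matrix(f0 * (1 + a$level), length(idx),
                           ncol(session$traces), byrow = TRUE)
      session$traces[idx, ] <- pmax(session$traces[idx, ], floor_vals)
    } else if (a$kind == "drift") {
      ramp <- seq(0, 1, length.out = length(idx)) * a$level
      add <- c(numeric(idx[1] - 1L), ramp,
               rep(a$level, n - idx[length(idx)]))
      session$traces <- session$traces +
        outer(add, f0 * 1)  # level is a dF/F fraction of each ROI's baseline
    } else {  # hemodip
      mid <- mean(range(idx))
      sdl <- (length(idx) / 4)
      bump <- a$level * exp(-((seq_len(n) - mid)^2) / (2 * sdl^2))
      session$traces <- session$traces - outer(bump, f0 * 1)
    }
  }
  prev <- attr(session, "artifacts")
  attr(session, "artifacts") <- rbind(prev, artifacts)
  session
}
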