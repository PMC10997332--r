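SCHEMA_VERSION <- "1.0"

fmt_num <- function(x) sprintf("%.17g", x)  # round-trips doubles exactly

write_num_csv <- function(mat, path) {
  df <- as.data.frame(mat)
  for (j in seq_along(df)) df[[j]] <- fmt_num(df[[j]])
  data.table::fwrite(df, path, quote = FALSE)
}

read_num_csv <- function(path) {
  dt <- data.table::fread(path, colClasses = "character",
                          showProgress = FALSE)
  m <- vapply(dt, as.numeric, numeric(nrow(dt)))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(dt),
                                 dimnames = list(NULL, names(dt)))
  m
}

#' Write a session container
#'
#' Serializes a session to a directory of plain-text files: `meta.json`,
#' `traces.csv` (one column per ROI), `behavior.csv` (`speed`, `flow`) and
#' `events.csv`. Numeric values are written with 17 significant digits, so
#' the round trip through [read_session()] is lossless.
#'
#' @param session A `cf_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "cf_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- session$meta
  meta$schema_version <- SCHEMA_VERSION
  meta$roi_ids <- colnames(session$traces)
  meta$n_samples <- nrow(session$traces)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_num_csv(session$traces, file.path(path, "traces.csv"))
  write_num_csv(cbind(speed = session$speed, flow = session$flow),
                file.path(path, "behavior.csv"))
  ev <- session$events
  if (is.null(ev) || nrow(ev) == 0L)
    ev <- data.frame(time_s = numeric(0), type = character(0),
                     duration_s = numeric(0))
  evw <- ev
  evw$time_s <- fmt_num(evw$time_s)
  if ("duration_s" %in% names(evw)) evw$duration_s <- fmt_num(evw$duration_s)
  data.table::fwrite(evw, file.path(path, "events.csv"), quote = FALSE)
  invisible(path)
}

#' Read a session container
#'
#' Inverse of [write_session()], with schema-version and consistency checks.
#'
#' @param path Session directory.
#' @return A `cf_session`.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("no session at ", path, call. = FALSE)
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("missing array: meta", call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(meta$schema_version, SCHEMA_VERSION))
    stop("unsupported container schema version: ",
         if (is.null(meta$schema_version)) "<none>" else meta$schema_version,
         " (supported: ", SCHEMA_VERSION, ")", call. = FALSE)
  tf <- file.path(path, "traces.csv")
  bf <- file.path(path, "behavior.csv")
  if (!file.exists(tf)) stop("missing array: traces", call. = FALSE)
  if (!file.exists(bf)) stop("missing array: behavior", call. = FALSE)
  traces <- read_num_csv(tf)
  beh <- read_num_csv(bf)
  for (arr in c("speed", "flow"))
    if (!arr %in% colnames(beh)) stop("missing array: ", arr, call. = FALSE)
  if (!identical(colnames(traces), unlist(meta$roi_ids)))
    stop("corrupted array: traces (ROI columns do not match metadata)",
         call. = FALSE)
  if (nrow(traces) != meta$n_samples || nrow(beh) != meta$n_samples)
    stop("corrupted array: ",
         if (nrow(traces) != meta$n_samples) "traces" else "behavior",
         " (length inconsistent with metadata)", call. = FALSE)
  ef <- file.path(path, "events.csv")
  ev <- if (file.exists(ef)) {
    d <- data.table::fread(ef, data.table = FALSE, showProgress = FALSE,
                           colClasses = list(character = "type"))
    if (nrow(d) == 0L)
      d <- data.frame(time_s = numeric(0), type = character(0),
                      duration_s = numeric(0))
    d$time_s <- as.numeric(d$time_s)
    if ("duration_s" %in% names(d)) d$duration_s <- as.numeric(d$duration_s)
    d
  } else data.frame(time_s = numeric(0), type = character(0),
                    duration_s = numeric(0))
  meta$fs_hz <- as.numeric(meta$fs_hz)
  keep <- setdiff(names(meta), c("roi_ids", "n_samples"))
  new_session(traces, as.numeric(beh[, "speed"]), as.numeric(beh[, "flow"]),
              ev, meta[keep])
}

#' Write a cohort to a directory of session containers
#'
#' One subdirectory per session plus a `ground_truth.json` sidecar with the
#' generator's injected parameters.
#'
#' @param cohort A `cf_cohort`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cf_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$sessions))
    write_session(cohort$sessions[[sid]], file.path(path, sid))
  truth <- cohort$truth
  truth$latent_loadings <- as.data.frame(truth$latent_loadings)
  jsonlite::write_json(truth, file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Default pipeline configuration
#'
#' Nested list of every analysis default, each overridable; unknown keys are
#' rejected. Thresholds are stored in the units used internally (dF/F as
#' fractions, speeds in cm/s, times in seconds).
#'
#' @param ... Named overrides, nested as in the defaults, e.g.
#'   `pipeline_config(qc = list(level = 0.25))`.
#' @return List of class `cf_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    detrend = list(window_s = 62.5, percentile = 0.08, enabled = TRUE),
    qc = list(level = 0.30, min_duration_s = 10),
    onsets = list(threshold_cms = 30, exclusion_window_s = 3,
                  quiescence_cms = 1),
    align = list(window_s = c(-5, 3), baseline_mode = "onset_gcamp"),
    similarity = list(smooth_s = 1, min_resp = 0.01),
    density = list(n_bins = 40, sigma_bins = 1, d_range = c(0, 1.6),
                   r_range = c(-0.25, 1)),
    drug = list(cutoff = 0.9, before = "naive", after = "drug"),
    boot = list(n_boot = 1000, ci = 0.90),
    seed = 1L
  )
  merge_cfg <- function(base, over, prefix = "") {
    for (nm in names(over)) {
      if (!nm %in% names(base))
        stop("unknown configuration key: ", prefix, nm, call. = FALSE)
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]],
                                paste0(prefix, nm, "."))
      } else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_cfg(defaults, list(...))
  stopifnot(cfg$detrend$window_s > 0, cfg$qc$level > 0,
            cfg$onsets$threshold_cms > 0, cfg$boot$n_boot >= 1)
  class(cfg) <- "cf_pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file with (a subset of) the [pipeline_config()] keys.
#' @return Validated `cf_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline over a directory of sessions
#'
#' Stages, in order: read -> dF/F + drift correction -> seizure QC -> onset
#' detection -> aligned averages (closed and open-loop locomotion onsets,
#' with hierarchical-bootstrap bands) -> closed/open similarity -> pairwise
#' ROI correlations and density map -> treatment-induced correlation change
#' (when both treatment labels are present). Every output carries the
#' configuration hash and seed; a machine-readable report counts exclusions
#' at every stage. A stage failure halts with the stage name and offending
#' session id.
#'
#' @param config A `cf_pipeline_config`.
#' @param in_dir Directory of session containers (subdirectories).
#' @param out_dir Output directory for CSV/JSON artifacts.
#' @param geometry ROI geometry used for distances.
#' @return The run report (list), invisibly written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config, in_dir, out_dir,
                         geometry = default_roi_geometry()) {
  stopifnot(inherits(config, "cf_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  report <- list(config_hash = hash, seed = config$seed, stages = list())
  set.seed(config$seed)

  paths <- list.dirs(in_dir, recursive = FALSE)
  if (length(paths) == 0L) {
    report$n_sessions <- 0L
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }

  stage <- function(name, sid, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed",
           if (!is.null(sid)) paste0(" for session ", sid), ": ",
           conditionMessage(e), call. = FALSE))
  }

  sessions <- lapply(paths, function(p) stage("read", basename(p),
                                              read_session(p)))
  names(sessions) <- vapply(sessions, function(s) s$meta$session_id, "")
  report$n_sessions <- length(sessions)

  # fail fast on config/session incompatibilities before any computation
  for (s in sessions)
    if (config$detrend$enabled &&
        round(config$detrend$window_s * s$meta$fs_hz) > nrow(s$traces))
      stop("pipeline stage 'validate' failed for session ",
           s$meta$session_id, ": detrend window longer than session",
           call. = FALSE)

  sessions <- lapply(sessions, function(s)
    stage("preprocess", s$meta$session_id,
          if (identical(s$meta$units, "raw"))
            preprocess_session(s, config$detrend$window_s,
                               config$detrend$percentile,
                               config$detrend$enabled) else s))

  qc <- stage("qc", NULL,
              qc_exclude_sessions(sessions, config$qc$level,
                                  config$qc$min_duration_s))
  data.table::fwrite(qc$report, file.path(out_dir, "qc_report.csv"))
  report$stages$qc <- list(excluded = sum(qc$report$excluded))
  sessions <- qc$kept

  ev_all <- list()
  aligned <- list(closed = list(), open = list())
  for (s in sessions) {
    sid <- s$meta$session_id
    cond <- s$meta$condition
    if (!cond %in% c("closed", "open")) next
    type <- paste0("loco_", cond)
    ev <- stage("events", sid,
                detect_onsets(s$speed, s$flow, s$meta$fs_hz,
                              config$onsets$threshold_cms,
                              config$onsets$exclusion_window_s,
                              config$onsets$quiescence_cms, type))
    if (nrow(ev) > 0)
      ev_all[[sid]] <- cbind(session_id = sid, as.data.frame(ev))
    if (any(ev$valid)) {
      al <- stage("align", sid,
                  extract_aligned(s$traces, ev, s$meta$fs_hz,
                                  config$align$window_s,
                                  mouse = s$meta$mouse_id, session = sid))
      if (dim(al$data)[1] > 0)
        aligned[[cond]][[sid]] <- baseline_subtract(
          al, config$align$baseline_mode)
    }
  }
  if (length(ev_all)) {
    evdf <- do.call(rbind, unname(ev_all))
    data.table::fwrite(evdf, file.path(out_dir, "events.csv"))
    report$stages$events <- list(candidates = nrow(evdf),
                                 valid = sum(evdf$valid))
  }

  trig <- list()
  for (cond in c("closed", "open")) {
    if (length(aligned[[cond]]) == 0L) next
    al <- combine_aligned(aligned[[cond]])
    trig[[cond]] <- stage("average", NULL,
                          triggered_average(al, config$boot$n_boot,
                                            config$boot$ci))
    dt <- data.table::data.table(
      roi = rep(al$roi_ids, times = dim(al$data)[3]),
      time_s = rep(trig[[cond]]$time_s, each = length(al$roi_ids)),
      mean = as.vector(trig[[cond]]$mean),
      ci_low = as.vector(trig[[cond]]$ci_low),
      ci_high = as.vector(trig[[cond]]$ci_high))
    data.table::fwrite(dt, file.path(out_dir,
                                     paste0("triggered_", cond, ".csv")))
  }
  if (!is.null(trig$closed) && !is.null(trig$open)) {
    sim <- stage("similarity", NULL,
                 onset_similarity(trig$closed, trig$open,
                                  config$similarity$smooth_s))
    data.table::fwrite(sim, file.path(out_dir, "similarity.csv"))
    report$stages$similarity <- attr(sim, "summary")
  }

  pairs <- do.call(rbind, lapply(sessions, function(s)
    stage("corr", s$meta$session_id,
          pairwise_roi_correlation(s, geometry))))
  data.table::fwrite(pairs, file.path(out_dir, "pair_correlations.csv"))
  report$stages$corr <- list(pairs = nrow(pairs),
                             missing = sum(pairs$missing))
  dens <- stage("density", NULL,
                correlation_distance_density(
                  pairs, config$density$n_bins, config$density$sigma_bins,
                  config$density$d_range, config$density$r_range))
  jsonlite::write_json(
    list(grid = dens$grid, smoothed = dens$smoothed,
         d_edges = dens$d_edges, r_edges = dens$r_edges,
         sigma_bins = dens$sigma_bins, contour_level = dens$contour_level,
         peak_density = dens$peak_density, n_pairs = dens$n_pairs,
         config_hash = hash),
    file.path(out_dir, "density.json"), auto_unbox = TRUE, digits = NA)

  trts <- unique(pairs$treatment)
  if (all(c(config$drug$before, config$drug$after) %in% trts)) {
    dc <- stage("drugchange", NULL,
                drug_change(pairs[pairs$treatment == config$drug$before, ],
                            pairs[pairs$treatment == config$drug$after, ],
                            config$drug$cutoff))
    data.table::fwrite(dc, file.path(out_dir, "drug_change.csv"))
    sm <- summary(dc)
    report$stages$drugchange <-
      list(n_short = sum(dc$range == "short"),
           n_long = sum(dc$range == "long"),
           median_short = sm["short", "median"],
           median_long = sm["long", "median"])
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
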