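# Small in-code fixtures shared across test files.

tiny_cfg <- function(...) {
  args <- utils::modifyList(list(n_mice = 2L, sessions_per_condition = 1L,
                                 session_duration_s = 120), list(...))
  do.call(sim_config, args)
}

# A dF/F session built directly from given arrays (bypasses the generator).
make_dff_session <- function(traces, speed = numeric(nrow(traces)),
                             flow = numeric(nrow(traces)), fs_hz = 100,
                             mouse_id = "m01", session_id = "s01",
                             condition = "closed", treatment = "naive") {
  corticoflow:::new_session(
    traces, speed, flow,
    data.frame(time_s = numeric(0), type = character(0),
               duration_s = numeric(0)),
    list(mouse_id = mouse_id, session_id = session_id, genotype = "l5it",
         condition = condition, treatment = treatment, fs_hz = fs_hz,
         indicator = "gcamp", units = "dff", bregma_lambda_mm = 4.2,
         schema_version = "1.0"))
}

zero_session <- function(n = 3000, fs_hz = 100, session_id = "s01") {
  rois <- default_roi_geometry()$roi
  tr <- matrix(0, n, length(rois), dimnames = list(NULL, rois))
  make_dff_session(tr, fs_hz = fs_hz, session_id = session_id)
}

# Pair-correlation table built by hand for metric tests.
make_pairs <- function(mouse, r, d_norm, roi_a = NULL, roi_b = NULL,
                       session = "s01", treatment = "naive") {
  k <- length(r)
  if (is.null(roi_a)) roi_a <- sprintf("A%02d", seq_len(k))
  if (is.null(roi_b)) roi_b <- sprintf("B%02d", seq_len(k))
  out <- data.frame(mouse = mouse, session = session, treatment = treatment,
                    condition = "dark", roi_a = roi_a, roi_b = roi_b,
                    r = r, d_norm = d_norm, missing = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("cf_paircors", "data.frame")
  out
}

# Aligned tensor with prescribed per-onset constant responses, one bin
# structure wide enough for every baseline mode.
make_aligned_constant <- function(values_by_onset, mice, fs_hz = 100,
                                  window_s = c(-5, 3), n_roi = 2) {
  nb <- round((window_s[2] - window_s[1]) * fs_hz)
  n_on <- length(values_by_onset)
  data <- array(rep(values_by_onset, n_roi * nb),
                dim = c(n_on, n_roi, nb),
                dimnames = list(NULL, paste0("roi", seq_len(n_roi)), NULL))
  structure(list(
    data = data,
    onset_info = data.frame(mouse = mice, session = "s01",
                            time_s = seq_len(n_on), type = "loco_closed",
                            stringsAsFactors = FALSE),
    window_s = window_s, bin_s = 1 / fs_hz,
    roi_ids = paste0("roi", seq_len(n_roi)),
    baselined = FALSE, baseline_window_s = NULL, n_dropped = 0L
  ), class = "cf_aligned")
}

# Triggered-average shell around given per-ROI mean curves.
make_triggered <- function(mean_mat, fs_hz = 100, window_s = c(-5, 3)) {
  nb <- ncol(mean_mat)
  structure(list(mean = mean_mat, ci_low = mean_mat, ci_high = mean_mat,
                 time_s = window_s[1] + (seq_len(nb) - 1L) / fs_hz,
                 window_s = window_s, bin_s = 1 / fs_hz,
                 roi_ids = rownames(mean_mat),
                 n_onsets = 1L, n_mice = 1L, ci = 0.9, n_boot = 0L),
            class = "cf_triggered")
}
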