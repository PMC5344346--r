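# shared fixtures: small synthetic datasets and hand-built segments

tiny_config <- function(seed = 1L, gain = 3, ...) {
  synthetic_config(n_subjects = 3L, segments_per_class = 6L,
                   sampling_rate = 64, window_seconds = 4,
                   effect_bands = data.frame(lo = 2, hi = 5, gain = gain),
                   seed = seed, ...)
}

make_segment <- function(x, fs = 64, label = "non-seizure", subject = "s1") {
  eeg_segment(x, fs, label, subject_id = subject)
}

# brute-force window labeling oracle, independent of segment_record():
# for every aligned full window, classify by sample-level interval membership
oracle_window_labels <- function(duration_s, window_s, intervals) {
  n_win <- floor(duration_s / window_s)
  out <- character(0)
  starts <- numeric(0)
  for (k in seq_len(n_win) - 1) {
    w0 <- k * window_s; w1 <- (k + 1) * window_s
    # sample the window densely and test membership in any interval
    ts <- seq(w0, w1 - 1e-9, by = 0.01)
    inside <- rep(FALSE, length(ts))
    for (r in seq_len(nrow(intervals))) {
      inside <- inside | (ts >= intervals$start_s[r] & ts < intervals$end_s[r])
    }
    lab <- if (all(inside)) "seizure" else if (!any(inside)) "non-seizure" else NA
    if (!is.na(lab)) { out <- c(out, lab); starts <- c(starts, w0) }
  }
  data.frame(start_s = starts, label = out)
}
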