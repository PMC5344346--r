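# Synthetic multi-subject EEG with controlled rhythm-band effects.
#
# Non-seizure segments are 1/f^beta Gaussian noise (the broadband background
# of scalp EEG); seizure segments add band-limited oscillatory power in
# configurable rhythm bands, scaled per subject, emulating ictal rhythmic
# activity as a power elevation rather than a spike-wave waveform shape.

#' Configuration for the synthetic EEG generator
#'
#' Defaults emulate a small multi-subject seizure-detection study: 6 subjects
#' contributing 20 segments per class each, 20 s windows at 256 Hz, a pink
#' (1/f) background, and one ictal effect — a gain-3 power elevation in the
#' 2–5 Hz (delta/theta) range, where rhythmic ictal activity is commonly
#' seen. Per-subject effect strength varies log-normally so that subject
#' identity matters, making leave-one-subject-out genuinely harder than
#' pooled k-fold.
#'
#' @param n_subjects number of subjects.
#' @param segments_per_class segments per class per subject.
#' @param sampling_rate Hz.
#' @param window_seconds segment duration.
#' @param background_exponent spectral slope beta of the 1/f^beta background.
#' @param effect_bands data.frame with columns `lo`, `hi` (Hz, within
#'   (0, Nyquist)) and `gain` (>= 0): each row adds a random-phase band-limited
#'   component to seizure segments with RMS amplitude `gain` times the
#'   background RMS within that band.
#' @param subject_gain_sd standard deviation (log scale) of the per-subject
#'   multiplicative effect gain.
#' @param amplitude_sd background amplitude (standard deviation, microvolts).
#' @param seed integer seed; the dataset is a pure function of the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 6L,
                             segments_per_class = 20L,
                             sampling_rate = 256,
                             window_seconds = 20,
                             background_exponent = 1,
                             effect_bands = data.frame(lo = 2, hi = 5, gain = 3),
                             subject_gain_sd = 0.3,
                             amplitude_sd = 30,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, segments_per_class >= 1,
            sampling_rate > 0, window_seconds > 0,
            is.data.frame(effect_bands),
            all(c("lo", "hi", "gain") %in% names(effect_bands)))
  if (nrow(effect_bands) > 0) {
    if (any(effect_bands$lo <= 0) || any(effect_bands$lo >= effect_bands$hi)) {
      stop("effect bands need 0 < lo < hi")
    }
    if (any(effect_bands$hi > sampling_rate / 2)) {
      stop("effect band above the Nyquist frequency (", sampling_rate / 2, " Hz)")
    }
    if (any(effect_bands$gain < 0)) stop("effect gains must be >= 0")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         segments_per_class = as.integer(segments_per_class),
         sampling_rate = sampling_rate, window_seconds = window_seconds,
         background_exponent = background_exponent,
         effect_bands = effect_bands,
         subject_gain_sd = subject_gain_sd,
         amplitude_sd = amplitude_sd, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# spectral amplitude envelope of the background over FFT bin frequencies
.pink_envelope <- function(freqs, beta) {
  env <- numeric(length(freqs))
  pos <- freqs > 0
  env[pos] <- freqs[pos]^(-beta / 2)
  env
}

# spectral synthesis: complex Gaussian bins shaped by env, back to time
# domain, scaled by the envelope's theoretical RMS (not the realized sample
# SD, which would suppress the natural segment-to-segment power variability)
.spectral_noise <- function(n, env) {
  spec <- env * (stats::rnorm(n) + 1i * stats::rnorm(n))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / (sqrt(sum(env^2)) / n)
}

# one 1/f^beta noise vector of length n, unit variance in expectation
.pink_noise <- function(n, fs, beta) {
  freqs <- c(seq(0, floor(n / 2)), -seq(ceiling(n / 2) - 1, 1)) * fs / n
  .spectral_noise(n, .pink_envelope(abs(freqs), beta))
}

# random-phase band-limited component, unit RMS in expectation
.band_component <- function(n, fs, lo, hi, beta) {
  freqs <- c(seq(0, floor(n / 2)), -seq(ceiling(n / 2) - 1, 1)) * fs / n
  in_band <- abs(freqs) >= lo & abs(freqs) <= hi
  if (!any(in_band)) stop("effect band (", lo, ", ", hi, ") Hz contains no FFT bin")
  .spectral_noise(n, .pink_envelope(abs(freqs), beta) * in_band)
}

# fraction of background variance lying in [lo, hi], from the envelope
.band_power_fraction <- function(n, fs, lo, hi, beta) {
  freqs <- c(seq(0, floor(n / 2)), -seq(ceiling(n / 2) - 1, 1)) * fs / n
  env2 <- .pink_envelope(abs(freqs), beta)^2
  in_band <- abs(freqs) >= lo & abs(freqs) <= hi
  sum(env2[in_band]) / sum(env2)
}

#' Generate a synthetic multi-subject labeled EEG dataset
#'
#' Non-seizure segments are `1/f^beta` Gaussian noise; seizure segments are
#' the same background plus, per effect band, a random-phase band-limited
#' component whose RMS equals `gain * subject_gain` times the background RMS
#' within that band. Classes are exactly balanced within every subject and
#' the full dataset is reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A list of [eeg_segment]s, grouped by subject, non-seizure before
#'   seizure within each subject.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)

  fs <- config$sampling_rate
  n <- round(config$window_seconds * fs)
  beta <- config$background_exponent
  eb <- config$effect_bands
  band_rms <- if (nrow(eb) > 0) {
    sqrt(vapply(seq_len(nrow(eb)), function(i) {
      .band_power_fraction(n, fs, eb$lo[i], eb$hi[i], beta)
    }, 1.0))
  } else numeric(0)

  segments <- list()
  offset <- 0
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    subj_gain <- exp(stats::rnorm(1, 0, config$subject_gain_sd))
    for (label in c("non-seizure", "seizure")) {
      for (k in seq_len(config$segments_per_class)) {
        x <- config$amplitude_sd * .pink_noise(n, fs, beta)
        if (label == "seizure" && nrow(eb) > 0) {
          for (i in seq_len(nrow(eb))) {
            amp <- eb$gain[i] * subj_gain * config$amplitude_sd * band_rms[i]
            x <- x + amp * .band_component(n, fs, eb$lo[i], eb$hi[i], beta)
          }
        }
        segments[[length(segments) + 1L]] <- eeg_segment(
          x, fs, label, subject_id = sid, channel = "synth",
          origin_offset_s = offset
        )
        offset <- offset + config$window_seconds
      }
    }
  }
  segments
}

#' Write a synthetic EDF record with embedded seizure intervals
#'
#' Builds a continuous multi-channel record whose samples inside
#' `seizure_intervals` carry the config's rhythm-band effects, writes it as a
#' 16-bit EDF file plus a matching annotation CSV
#' (`subject_id,record_id,start_s,end_s`), and returns the paths. Intended
#' for end-to-end I/O tests and demos of the EDF pathway.
#'
#' @param config a [synthetic_config()] (its `sampling_rate`,
#'   `background_exponent`, `effect_bands`, `amplitude_sd` and `seed` are
#'   used).
#' @param path output EDF file path.
#' @param duration_s record duration (whole seconds).
#' @param n_channels number of channels.
#' @param seizure_intervals data.frame with `start_s`, `end_s` in seconds.
#' @param subject_id identifier stored in the EDF patient field.
#' @param annotations_path output CSV; default `<path>.annotations.csv`.
#' @return Invisibly, a list with `edf`, `annotations` paths.
#' @export
make_fixture_edf <- function(config, path, duration_s = 120,
                             n_channels = 2L,
                             seizure_intervals = data.frame(start_s = 40,
                                                            end_s = 70),
                             subject_id = "SYN01",
                             annotations_path = paste0(path, ".annotations.csv")) {
  stopifnot(inherits(config, "synthetic_config"))
  iv <- .normalize_intervals(seizure_intervals, duration_s)
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)

  fs <- config$sampling_rate
  n <- round(duration_s * fs)
  beta <- config$background_exponent
  eb <- config$effect_bands
  samples <- matrix(0, nrow = n, ncol = n_channels)
  for (ch in seq_len(n_channels)) {
    x <- config$amplitude_sd * .pink_noise(n, fs, beta)
    if (nrow(iv) > 0 && nrow(eb) > 0) {
      for (r in seq_len(nrow(iv))) {
        rows <- seq.int(floor(iv$start_s[r] * fs) + 1L,
                        min(n, ceiling(iv$end_s[r] * fs)))
        for (i in seq_len(nrow(eb))) {
          frac <- .band_power_fraction(length(rows), fs, eb$lo[i], eb$hi[i], beta)
          amp <- eb$gain[i] * config$amplitude_sd * sqrt(frac)
          x[rows] <- x[rows] +
            amp * .band_component(length(rows), fs, eb$lo[i], eb$hi[i], beta)
        }
      }
    }
    samples[, ch] <- x
  }
  .write_edf(path, samples, fs, paste0("EEG", seq_len(n_channels)),
             patient = subject_id)
  utils::write.csv(
    data.frame(subject_id = subject_id, record_id = basename(path),
               start_s = iv$start_s, end_s = iv$end_s),
    annotations_path, row.names = FALSE
  )
  invisible(list(edf = path, annotations = annotations_path))
}

#' Read a seizure-annotation CSV
#'
#' Expected columns: `subject_id`, `record_id`, `start_s`, `end_s`.
#'
#' @param path CSV file.
#' @param record_id optionally filter to one record.
#' @return data.frame with `start_s`, `end_s` (possibly zero rows).
#' @export
read_annotations_csv <- function(path, record_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "record_id", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!is.null(record_id)) df <- df[df$record_id == record_id, , drop = FALSE]
  df[, c("start_s", "end_s"), drop = FALSE]
}
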