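#' Construct a labeled EEG segment
#'
#' A segment is one fixed-duration single-channel window with a binary
#' seizure/non-seizure label.
#'
#' @param samples numeric vector.
#' @param sampling_rate in Hz (positive).
#' @param label `"seizure"` or `"non-seizure"`.
#' @param subject_id,channel identifiers.
#' @param origin_offset_s seconds from the start of the source record.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, sampling_rate, label,
                        subject_id = "s1", channel = "ch1",
                        origin_offset_s = 0) {
  stopifnot(is.numeric(samples), length(samples) > 0L,
            is.numeric(sampling_rate), sampling_rate > 0)
  label <- match.arg(label, c("seizure", "non-seizure"))
  structure(
    list(subject_id = as.character(subject_id), channel = as.character(channel),
         samples = as.numeric(samples), sampling_rate = sampling_rate,
         label = label, origin_offset_s = origin_offset_s),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s/%s: %d samples @ %g Hz (%.2f s), label %s, offset %g s\n",
              x$subject_id, x$channel, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$label, x$origin_offset_s))
  invisible(x)
}

#' Read a single-column ASCII EEG segment (UBonn style)
#'
#' The Bonn archive distributes 23.6 s single-channel segments as plain text,
#' one integer sample per line, recorded at 173.61 Hz.
#'
#' @param path text file with one numeric sample per line.
#' @param sampling_rate in Hz; the archive's rate by default.
#' @param label `"seizure"` (set E) or `"non-seizure"` (sets C, D).
#' @param subject_id,channel identifiers attached to the segment.
#' @return An [eeg_segment].
#' @export
read_ubonn_segment <- function(path, sampling_rate = 173.61, label,
                               subject_id = basename(path), channel = "ch1") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty segment file: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop("non-numeric sample at line ", bad, " of ", path, ": '", lines[bad], "'")
  }
  eeg_segment(vals, sampling_rate, label, subject_id = subject_id,
              channel = channel)
}

# ---- seizure intervals -----------------------------------------------------

# normalize to a sorted, merged, half-open [start, end) interval table
.normalize_intervals <- function(intervals, duration_s = Inf) {
  if (is.null(intervals) || (is.data.frame(intervals) && nrow(intervals) == 0L) ||
      (!is.data.frame(intervals) && length(intervals) == 0L)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  if (is.matrix(intervals)) {
    intervals <- data.frame(start_s = intervals[, 1], end_s = intervals[, 2])
  }
  stopifnot(is.data.frame(intervals), all(c("start_s", "end_s") %in% names(intervals)))
  iv <- intervals[, c("start_s", "end_s")]
  if (any(!is.finite(iv$start_s)) || any(!is.finite(iv$end_s))) {
    stop("seizure intervals must be finite")
  }
  if (any(iv$start_s >= iv$end_s)) {
    stop("invalid seizure interval: start must be < end")
  }
  if (any(iv$start_s < 0) || any(iv$end_s > duration_s)) {
    stop("seizure interval outside the record (duration ", duration_s, " s)")
  }
  iv <- iv[order(iv$start_s), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv$start_s[i] <= merged$end_s[last]) {
      merged$end_s[last] <- max(merged$end_s[last], iv$end_s[i])
    } else {
      merged <- rbind(merged, iv[i, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Construct a multi-channel EEG record
#'
#' @param subject_id identifier.
#' @param samples numeric matrix, samples in rows and channels in columns
#'   (a plain vector is taken as one channel).
#' @param sampling_rate in Hz.
#' @param channel_labels character vector, one per column.
#' @param seizure_intervals data.frame with `start_s`, `end_s` columns (or a
#'   two-column matrix) in seconds; intervals are validated against the
#'   record duration, sorted, and overlaps merged. Half-open `[start, end)`.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(subject_id, samples, sampling_rate,
                       channel_labels = NULL, seizure_intervals = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  stopifnot(is.matrix(samples), is.numeric(sampling_rate), sampling_rate > 0)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(ncol(samples)))
  }
  stopifnot(length(channel_labels) == ncol(samples))
  duration <- nrow(samples) / sampling_rate
  structure(
    list(subject_id = as.character(subject_id),
         channel_labels = as.character(channel_labels),
         samples = samples, sampling_rate = sampling_rate,
         seizure_intervals = .normalize_intervals(seizure_intervals, duration)),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s: %d channel(s) x %d samples @ %g Hz (%.1f s), %d seizure interval(s)\n",
              x$subject_id, ncol(x$samples), nrow(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate, nrow(x$seizure_intervals)))
  invisible(x)
}

#' Read an EDF record and attach seizure annotations
#'
#' Reads a standard 16-bit European Data Format file. All signals must share
#' one sampling rate. Annotations are supplied separately (start/end seconds),
#' as in the CHB-MIT distribution where they accompany the recordings.
#'
#' @param path EDF file.
#' @param seizure_intervals data.frame with `start_s`, `end_s` (seconds) or
#'   two-column matrix; `NULL` for none.
#' @param subject_id defaults to the EDF local patient identification field
#'   (or the file name when blank).
#' @return An [eeg_record].
#' @export
read_edf_record <- function(path, seizure_intervals = NULL, subject_id = NULL) {
  edf <- .read_edf(path)
  if (is.null(subject_id)) {
    subject_id <- if (nzchar(edf$patient)) edf$patient else basename(path)
  }
  eeg_record(subject_id, edf$samples, edf$sampling_rate,
             channel_labels = edf$channel_labels,
             seizure_intervals = seizure_intervals)
}

#' FIR high-pass filtering of a segment or record
#'
#' Removes low-frequency drift with a linear-phase FIR high-pass designed by
#' the window method (Hamming window) at the given order and cutoff — the
#' standard preprocessing for scalp EEG prior to wavelet analysis. Filtering
#' is single-pass causal (zero initial conditions), so the output has a
#' start-up transient of `order` samples and a constant group delay of
#' `order/2` samples.
#'
#' @param segment an [eeg_segment] or [eeg_record].
#' @param order filter order (even, positive); the filter has `order + 1` taps.
#' @param cutoff high-pass cutoff in Hz, below the Nyquist frequency.
#' @return An object of the same class with filtered samples (same length).
#' @export
highpass_filter <- function(segment, order = 48L, cutoff = 0.5) {
  fs <- segment$sampling_rate
  if (!(order > 0 && order %% 2 == 0)) stop("order must be even and positive")
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie in (0, Nyquist) = (0, ", fs / 2, ") Hz")
  }
  b <- signal::fir1(order, cutoff / (fs / 2), type = "high",
                    window = signal::hamming(order + 1L))
  b <- as.numeric(b)
  apply_fir <- function(x) .conv_full(x, b)[seq_along(x)]
  if (inherits(segment, "eeg_segment")) {
    segment$samples <- apply_fir(segment$samples)
  } else if (inherits(segment, "eeg_record")) {
    segment$samples <- apply(segment$samples, 2L, apply_fir)
  } else {
    stop("segment must be an eeg_segment or eeg_record")
  }
  segment
}

#' Window a record into labeled fixed-length segments
#'
#' Slides a non-overlapping window of `window_seconds` over each channel,
#' aligned to multiples of the window from the record start. A window fully
#' inside a seizure interval is labeled `"seizure"`; a window that overlaps
#' no interval is `"non-seizure"`; windows straddling an interval boundary
#' are discarded (avoiding label noise at onsets/offsets), as is a trailing
#' partial window. Intervals and windows are half-open `[start, end)`.
#'
#' @param record an [eeg_record].
#' @param window_seconds window duration; `window_seconds * sampling_rate`
#'   must be a whole number of samples.
#' @return A list of [eeg_segment]s (possibly empty).
#' @export
segment_record <- function(record, window_seconds = 20) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$sampling_rate
  wlen <- window_seconds * fs
  if (abs(wlen - round(wlen)) > 1e-9) {
    stop("window_seconds * sampling_rate must be a whole number of samples")
  }
  wlen <- as.integer(round(wlen))
  n <- nrow(record$samples)
  n_windows <- n %/% wlen
  if (n_windows == 0L) return(list())
  iv <- record$seizure_intervals
  out <- list()
  for (k in seq_len(n_windows) - 1L) {
    w_start <- k * window_seconds
    w_end <- (k + 1) * window_seconds
    inside <- nrow(iv) > 0L && any(iv$start_s <= w_start & w_end <= iv$end_s)
    overlaps <- nrow(iv) > 0L && any(iv$start_s < w_end & w_start < iv$end_s)
    if (overlaps && !inside) next   # straddles a boundary
    label <- if (inside) "seizure" else "non-seizure"
    rows <- seq.int(k * wlen + 1L, (k + 1L) * wlen)
    for (ch in seq_along(record$channel_labels)) {
      out[[length(out) + 1L]] <- eeg_segment(
        record$samples[rows, ch], fs, label,
        subject_id = record$subject_id,
        channel = record$channel_labels[ch],
        origin_offset_s = w_start
      )
    }
  }
  out
}

#' Balance seizure/non-seizure counts within each subject
#'
#' For every subject, the majority class is subsampled uniformly at random
#' (seeded) so both classes contribute equally — mirroring per-subject
#' balancing of long-term recordings where non-seizure data dominates.
#' Subjects missing one class entirely are dropped with a warning.
#'
#' @param segments list of [eeg_segment]s.
#' @param seed integer seed for the subsampling.
#' @return A list of [eeg_segment]s, in original order.
#' @export
balance_classes <- function(segments, seed = 1L) {
  stopifnot(is.list(segments))
  if (length(segments) == 0L) return(segments)
  subj <- vapply(segments, `[[`, "", "subject_id")
  lab <- vapply(segments, `[[`, "", "label")
  keep <- logical(length(segments))
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  for (s in sort(unique(subj))) {
    i_seiz <- which(subj == s & lab == "seizure")
    i_non <- which(subj == s & lab == "non-seizure")
    if (length(i_seiz) == 0L || length(i_non) == 0L) {
      warning("subject '", s, "' lacks one class; excluded from balanced set")
      next
    }
    n <- min(length(i_seiz), length(i_non))
    keep[sample(i_seiz, n)] <- TRUE
    keep[sample(i_non, n)] <- TRUE
  }
  segments[keep]
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Recording hours represented by a set of fixed-length segments
#'
#' @param n_segments number of segments.
#' @param window_seconds duration of each segment.
#' @return Hours, as a number.
#' @export
#' @examples
#' segment_hours(6923, 20) # 38.46 h
segment_hours <- function(n_segments, window_seconds = 20) {
  n_segments * window_seconds / 3600
}

#' Export segments' metadata and samples to CSV
#'
#' One row per segment: `subject_id`, `channel`, `label`, `origin_offset_s`,
#' `sampling_rate`, then sample values in columns `s1..sN`.
#'
#' @param segments list of [eeg_segment]s of equal length.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(segments, path) {
  stopifnot(length(segments) > 0L)
  lens <- vapply(segments, function(s) length(s$samples), 1L)
  if (length(unique(lens)) != 1L) stop("segments must have equal length")
  meta <- data.frame(
    subject_id = vapply(segments, `[[`, "", "subject_id"),
    channel = vapply(segments, `[[`, "", "channel"),
    label = vapply(segments, `[[`, "", "label"),
    origin_offset_s = vapply(segments, `[[`, 1.0, "origin_offset_s"),
    sampling_rate = vapply(segments, `[[`, 1.0, "sampling_rate")
  )
  mat <- t(vapply(segments, `[[`, numeric(lens[1]), "samples"))
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  utils::write.csv(cbind(meta, as.data.frame(mat)), path, row.names = FALSE)
  invisible(path)
}

#' Read segments written by [write_segments_csv()]
#'
#' @param path CSV file.
#' @return A list of [eeg_segment]s.
#' @export
read_segments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  scols <- grep("^s[0-9]+$", names(df))
  lapply(seq_len(nrow(df)), function(i) {
    eeg_segment(as.numeric(df[i, scols]), df$sampling_rate[i], df$label[i],
                subject_id = df$subject_id[i], channel = df$channel[i],
                origin_offset_s = df$origin_offset_s[i])
  })
}
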