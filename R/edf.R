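# Minimal European Data Format (EDF, 16-bit) reader and writer.
# Supports the standard fixed-layout header and continuous records with one
# common sampling rate across signals, which covers CHB-MIT-style scalp EEG
# exports and the synthetic fixtures written by make_fixture_edf().

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'")
  formatC(x, width = -width, flag = " ")
}

.write_edf <- function(path, samples, sampling_rate, channel_labels,
                       patient = "X", recording = "synthetic",
                       physical_unit = "uV") {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  ns <- ncol(samples)
  stopifnot(length(channel_labels) == ns)
  if (abs(sampling_rate - round(sampling_rate)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate (1 s records)")
  }
  spr <- as.integer(round(sampling_rate))     # samples per 1 s record
  n_records <- nrow(samples) %/% spr
  if (n_records * spr != nrow(samples)) {
    stop("signal length must be a whole number of 1 s records")
  }
  phys_min <- floor(min(samples, -1))
  phys_max <- ceiling(max(samples, 1))
  dig_min <- -32768L; dig_max <- 32767L
  scale <- (dig_max - dig_min) / (phys_max - phys_min)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad(patient, 80), .edf_pad(recording, 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256L + ns * 256L, 8), .edf_pad("", 44),
    .edf_pad(n_records, 8), .edf_pad(1L, 8), .edf_pad(ns, 4)
  )
  field <- function(vals, width) paste(vapply(vals, .edf_pad, "", width), collapse = "")
  hdr <- paste0(
    hdr,
    field(channel_labels, 16), field(rep("", ns), 80),
    field(rep(physical_unit, ns), 8),
    field(rep(phys_min, ns), 8), field(rep(phys_max, ns), 8),
    field(rep(dig_min, ns), 8), field(rep(dig_max, ns), 8),
    field(rep("", ns), 80), field(rep(spr, ns), 8), field(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  dig <- round((samples - phys_min) * scale) + dig_min
  dig[dig > dig_max] <- dig_max; dig[dig < dig_min] <- dig_min
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_records)) {
    rows <- seq.int((r - 1L) * spr + 1L, r * spr)
    for (ch in seq_len(ns)) {
      writeBin(dig[rows, ch], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readChar(con, width, useBytes = TRUE)
    if (length(raw) == 0L || nchar(raw, type = "bytes") < width) {
      stop("truncated EDF header in ", path)
    }
    trimws(raw)
  }
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "'): ", path)
  patient <- rd(80); recording <- rd(80)
  rd(8); rd(8)                                 # start date / time
  header_bytes <- as.integer(rd(8)); rd(44)
  n_records <- as.integer(rd(8))
  record_duration <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("bad EDF header (number of signals): ", path)
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16); fields(80); fields(8)
  phys_min <- as.numeric(fields(8)); phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8)); dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8)); fields(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr)) ||
      is.na(header_bytes) || header_bytes != 256L + 256L * ns) {
    stop("mismatched EDF header in ", path)
  }
  if (length(unique(spr)) != 1L) {
    stop("EDF signals with differing sampling rates are not supported: ", path)
  }
  sampling_rate <- spr[1] / record_duration
  samples <- matrix(0, nrow = n_records * spr[1], ncol = ns)
  for (r in seq_len(n_records)) {
    rows <- seq.int((r - 1L) * spr[1] + 1L, r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little", signed = TRUE)
      if (length(dig) < spr[ch]) stop("truncated EDF data in ", path)
      samples[rows, ch] <- (dig - dig_min[ch]) *
        (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch]) +
        phys_min[ch]
    }
  }
  list(patient = patient, recording = recording, channel_labels = labels,
       samples = samples, sampling_rate = sampling_rate)
}
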