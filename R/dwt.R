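# Mallat multilevel filter bank with symmetric (half-point) boundary
# extension. Conventions (extension length F-1 per side, downsampling phase,
# output length floor((N+F-1)/2), reconstruction trim F-2) follow the common
# pyramid-algorithm implementation so coefficients are comparable across
# tools.

# symmetric half-point extension: pad p samples on each side, reflecting
# repeatedly when p exceeds the signal length
.sym_ext <- function(x, p) {
  n <- length(x)
  idx <- (seq.int(-p, n + p - 1L)) %% (2L * n)
  idx <- ifelse(idx >= n, 2L * n - 1L - idx, idx)
  x[idx + 1L]
}

# linear convolution a * b (full); direct tap loop — for the short filters
# used here this beats FFT convolution at the awkward lengths involved
.conv_full <- function(a, b) {
  na <- length(a); nb <- length(b)
  out <- numeric(na + nb - 1L)
  for (j in seq_len(nb)) {
    idx <- seq.int(j, length.out = na)
    out[idx] <- out[idx] + b[j] * a
  }
  out
}

# one analysis step: returns approximation and detail coefficient vectors
.dwt_step <- function(x, lo, hi) {
  f <- length(lo)
  n_out <- (length(x) + f - 1L) %/% 2L
  ext <- .sym_ext(x, f - 1L)
  take <- seq.int(f + 1L, by = 2L, length.out = n_out)
  list(a = .conv_full(ext, lo)[take], d = .conv_full(ext, hi)[take])
}

# one synthesis step: invert .dwt_step given the original length
.idwt_step <- function(ca, cd, rec_lo, rec_hi, out_len) {
  f <- length(rec_lo)
  up_a <- numeric(2L * length(ca)); up_a[seq(1L, by = 2L, along.with = ca)] <- ca
  up_d <- numeric(2L * length(cd)); up_d[seq(1L, by = 2L, along.with = cd)] <- cd
  s <- .conv_full(up_a, rec_lo) + .conv_full(up_d, rec_hi)
  s[seq.int(f - 1L, length.out = out_len)]
}

#' Frequency intervals of the dyadic bands
#'
#' For a source signal occupying `(a, b)` Hz, a level-`j` dyadic decomposition
#' tiles that range: the detail band at level `n` spans
#' `(a + (b-a)/2^n, a + (b-a)/2^(n-1))` and the final approximation band
#' spans `(a, a + (b-a)/2^j)`. Band index equals the detail level, so band 1
#' is the highest-frequency band and band `j+1` is the approximation.
#'
#' @param a,b lower and upper frequency of the source range in Hz
#'   (`0 <= a < b`).
#' @param level decomposition level `j >= 1`.
#' @return A data.frame with columns `band_index` (1..j+1), `kind`
#'   (`"detail"`/`"approximation"`), `freq_lo`, `freq_hi` in Hz.
#' @export
#' @examples
#' band_frequencies(0.5, 128, 3)
band_frequencies <- function(a, b, level) {
  stopifnot(length(a) == 1L, length(b) == 1L, length(level) == 1L)
  if (!(a >= 0 && a < b)) stop("need 0 <= a < b")
  if (level < 1) stop("level must be >= 1")
  level <- as.integer(level)
  n <- seq_len(level)
  lo <- a + (b - a) / 2^n
  hi <- a + (b - a) / 2^(n - 1)
  data.frame(
    band_index = c(n, level + 1L),
    kind = c(rep("detail", level), "approximation"),
    freq_lo = c(lo, a),
    freq_hi = c(hi, a + (b - a) / 2^level)
  )
}

#' Multilevel dyadic wavelet decomposition of an EEG segment
#'
#' Decomposes a segment into `level` detail bands plus one approximation band
#' using the pyramid (Mallat) algorithm with symmetric boundary extension.
#' Frequency intervals are attached per band via [band_frequencies()] over
#' `source_range`.
#'
#' @param segment an [eeg_segment] or a numeric vector.
#' @param wavelet a catalog member name, see [wavelet_catalog()].
#' @param level decomposition level, between 1 and
#'   [max_decomposition_level()] for this signal/wavelet.
#' @param sampling_rate required when `segment` is a bare numeric vector.
#' @param source_range frequency range `(a, b)` in Hz occupied by the signal;
#'   defaults to `c(0.5, sampling_rate/2)` — 0.5 Hz being the conventional
#'   high-pass cutoff applied during preprocessing.
#' @return An object of class `band_decomposition`: a list with `wavelet`,
#'   `family`, `level`, `sampling_rate`, `source_range`, `input_lengths`
#'   (per-level signal lengths, needed for reconstruction) and `bands`, a
#'   list of bands ordered by index, each with `index`, `kind`,
#'   `coefficients`, `freq_lo`, `freq_hi`.
#' @seealso [reconstruct()], [band_table()]
#' @export
decompose <- function(segment, wavelet, level, sampling_rate = NULL,
                      source_range = NULL) {
  if (inherits(segment, "eeg_segment")) {
    x <- segment$samples
    fs <- segment$sampling_rate
  } else {
    x <- as.numeric(segment)
    if (is.null(sampling_rate)) stop("sampling_rate is required for a bare numeric segment")
    fs <- sampling_rate
  }
  flt <- wavelet_filters(wavelet)
  max_lev <- max_decomposition_level(length(x), flt$length)
  level <- as.integer(level)
  if (level < 1L || level > max_lev) {
    stop("level must be in 1..", max_lev, " for ", wavelet,
         " on a ", length(x), "-sample segment")
  }
  if (is.null(source_range)) source_range <- c(0.5, fs / 2)
  freqs <- band_frequencies(source_range[1], source_range[2], level)

  details <- vector("list", level)
  lengths <- integer(level)
  cur <- x
  for (l in seq_len(level)) {
    lengths[l] <- length(cur)
    step <- .dwt_step(cur, flt$dec_lo, flt$dec_hi)
    details[[l]] <- step$d
    cur <- step$a
  }
  bands <- vector("list", level + 1L)
  for (l in seq_len(level)) {
    bands[[l]] <- list(index = l, kind = "detail", coefficients = details[[l]],
                       freq_lo = freqs$freq_lo[l], freq_hi = freqs$freq_hi[l])
  }
  bands[[level + 1L]] <- list(index = level + 1L, kind = "approximation",
                              coefficients = cur,
                              freq_lo = freqs$freq_lo[level + 1L],
                              freq_hi = freqs$freq_hi[level + 1L])
  structure(
    list(wavelet = wavelet, family = .wavelet_family(wavelet), level = level,
         sampling_rate = fs, source_range = source_range,
         input_lengths = lengths, bands = bands),
    class = "band_decomposition"
  )
}

.wavelet_family <- function(wavelet) {
  cat54 <- wavelet_catalog()
  cat54$family[match(wavelet, cat54$wavelet)]
}

#' Invert a band decomposition
#'
#' Runs the synthesis filter bank over the stored bands; for the orthogonal
#' and biorthogonal filters in the catalog this reproduces the analyzed
#' signal to numerical precision.
#'
#' @param decomposition a `band_decomposition` from [decompose()].
#' @return Numeric vector of the same length as the analyzed segment.
#' @export
reconstruct <- function(decomposition) {
  stopifnot(inherits(decomposition, "band_decomposition"))
  flt <- wavelet_filters(decomposition$wavelet)
  level <- decomposition$level
  cur <- decomposition$bands[[level + 1L]]$coefficients
  for (l in seq.int(level, 1L)) {
    cur <- .idwt_step(cur, decomposition$bands[[l]]$coefficients,
                      flt$rec_lo, flt$rec_hi,
                      decomposition$input_lengths[l])
  }
  cur
}

#' EEG rhythms overlapping a frequency band
#'
#' Conventional rhythm ranges: delta (0–4 Hz), theta (4–7 Hz), alpha
#' (8–15 Hz), beta (16–31 Hz) and gamma (above 31 Hz). A rhythm is reported
#' when its open interval intersects the band's open interval; note the
#' printed ranges leave 7–8 Hz and 15–16 Hz unassigned.
#'
#' @param band a band from a [decompose()] result, or a numeric vector
#'   `c(freq_lo, freq_hi)` in Hz.
#' @return Character vector of rhythm names (possibly empty), in
#'   delta..gamma order.
#' @export
#' @examples
#' rhythm_overlap(c(64.25, 128)) # "gamma"
#' rhythm_overlap(c(2, 5))       # "delta" "theta"
rhythm_overlap <- function(band) {
  if (is.list(band)) {
    lo <- band$freq_lo; hi <- band$freq_hi
  } else {
    stopifnot(is.numeric(band), length(band) == 2L)
    lo <- band[1]; hi <- band[2]
  }
  stopifnot(lo < hi)
  rhythms <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(0, 4, 8, 16, 31),
    hi = c(4, 7, 15, 31, Inf)
  )
  hit <- lo < rhythms$hi & rhythms$lo < hi
  rhythms$name[hit]
}

#' Summary table of a decomposition's bands
#'
#' @param decomposition a `band_decomposition`.
#' @return A data.frame with `band_index`, `kind`, `freq_lo`, `freq_hi`,
#'   `n_coefficients` and `rhythms` (comma-separated overlapping rhythm
#'   names), suitable for CSV export.
#' @export
band_table <- function(decomposition) {
  stopifnot(inherits(decomposition, "band_decomposition"))
  do.call(rbind, lapply(decomposition$bands, function(b) {
    data.frame(
      band_index = b$index, kind = b$kind,
      freq_lo = b$freq_lo, freq_hi = b$freq_hi,
      n_coefficients = length(b$coefficients),
      rhythms = paste(rhythm_overlap(b), collapse = ",")
    )
  }))
}

#' @export
print.band_decomposition <- function(x, ...) {
  cat(sprintf("<band_decomposition> %s, level %d (%d bands), %g Hz, range (%g, %g) Hz\n",
              x$wavelet, x$level, x$level + 1L, x$sampling_rate,
              x$source_range[1], x$source_range[2]))
  print(band_table(x), row.names = FALSE)
  invisible(x)
}
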