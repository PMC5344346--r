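#' The nine per-band coefficient features, in canonical order
#'
#' @return `c("Max","Min","Mean","STD","skewness","kurtosis","Energy","nSTD","nEnergy")`
#' @export
feature_names <- function() {
  c("Max", "Min", "Mean", "STD", "skewness", "kurtosis", "Energy",
    "nSTD", "nEnergy")
}

.check_features <- function(features) {
  all_f <- feature_names()
  if (length(features) == 0L) stop("feature set must be non-empty")
  if (anyDuplicated(features)) stop("duplicate feature names")
  bad <- setdiff(features, all_f)
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  # canonical order regardless of how the subset was written
  all_f[all_f %in% features]
}

#' Statistical features of one band's coefficients
#'
#' Computes the requested subset of the nine per-band statistics:
#' `Max`, `Min`, `Mean`; `STD` (sample standard deviation, n-1 denominator);
#' `skewness` and `kurtosis` (standardized 3rd/4th central moments with the
#' population n denominator; kurtosis is not excess-corrected, so a normal
#' sample gives ~3); `Energy` (sum of squared coefficients); `nSTD`
#' (`STD/(Max-Min)`) and `nEnergy` (`Energy/n`, energy per coefficient).
#' Degenerate inputs (constant band, or fewer than 2 coefficients) yield 0
#' for the moment-based and ratio features rather than an error, so
#' exhaustive searches never abort on a pathological band.
#'
#' @param coefficients non-empty numeric vector.
#' @param features subset of [feature_names()] (any order; evaluated in
#'   canonical order).
#' @return Named numeric vector in canonical feature order.
#' @export
#' @examples
#' band_features(c(1, 2, 3, 4))
band_features <- function(coefficients, features = feature_names()) {
  x <- as.numeric(coefficients)
  if (length(x) == 0L) stop("coefficients must be non-empty")
  features <- .check_features(features)
  n <- length(x)
  mx <- max(x); mn <- min(x); mu <- mean(x)
  energy <- sum(x^2)
  if (n < 2L || mx == mn) {
    s <- 0; skew <- 0; kurt <- 0; nstd <- 0
  } else {
    s <- stats::sd(x)
    m2 <- mean((x - mu)^2)
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
    nstd <- s / (mx - mn)
  }
  vals <- c(Max = mx, Min = mn, Mean = mu, STD = s, skewness = skew,
            kurtosis = kurt, Energy = energy, nSTD = nstd, nEnergy = energy / n)
  vals[features]
}

#' Feature vector of a decomposition over chosen bands and features
#'
#' Lays out features bands-major: all requested features of the lowest
#' selected band index first, then the next band, and so on. Positions are
#' named `b<band>_<feature>`.
#'
#' @param decomposition a `band_decomposition` from [decompose()].
#' @param band_subset integer band indices (subset of `1..level+1`); all
#'   bands by default.
#' @param features subset of [feature_names()].
#' @return Named numeric vector of length
#'   `length(band_subset) * length(features)`, with a `"layout"` attribute
#'   (data.frame of `band_index`, `feature` per position).
#' @export
assemble_feature_vector <- function(decomposition, band_subset = NULL,
                                    features = feature_names()) {
  stopifnot(inherits(decomposition, "band_decomposition"))
  n_bands <- decomposition$level + 1L
  if (is.null(band_subset)) band_subset <- seq_len(n_bands)
  band_subset <- as.integer(band_subset)
  if (length(band_subset) == 0L) stop("band subset must be non-empty")
  if (anyDuplicated(band_subset)) stop("duplicate band indices")
  if (any(band_subset < 1L | band_subset > n_bands)) {
    stop("band indices must be in 1..", n_bands)
  }
  band_subset <- sort(band_subset)
  features <- .check_features(features)
  vals <- unlist(lapply(band_subset, function(b) {
    v <- band_features(decomposition$bands[[b]]$coefficients, features)
    names(v) <- paste0("b", b, "_", features)
    v
  }))
  attr(vals, "layout") <- data.frame(
    band_index = rep(band_subset, each = length(features)),
    feature = rep(features, times = length(band_subset))
  )
  vals
}

#' Feature matrix for a set of segments under one wavelet/level
#'
#' Decomposes each segment once and assembles its feature vector; the
#' resulting matrix is the cache sliced by the subset searches.
#'
#' @param segments list of [eeg_segment]s of equal length and rate.
#' @param wavelet,level passed to [decompose()].
#' @param band_subset,features passed to [assemble_feature_vector()].
#' @param source_range passed to [decompose()].
#' @return A list with `x` (numeric matrix, one row per segment, columns
#'   named `b<band>_<feature>`), `label` (character), `subject` (character).
#' @export
segment_features <- function(segments, wavelet, level, band_subset = NULL,
                             features = feature_names(), source_range = NULL) {
  stopifnot(is.list(segments), length(segments) > 0L)
  rows <- lapply(segments, function(seg) {
    dec <- decompose(seg, wavelet, level, source_range = source_range)
    assemble_feature_vector(dec, band_subset, features)
  })
  x <- do.call(rbind, rows)
  list(x = x,
       label = vapply(segments, `[[`, "", "label"),
       subject = vapply(segments, `[[`, "", "subject_id"))
}

#' Export a feature matrix with labels to CSV
#'
#' @param feats result of [segment_features()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(feats, path) {
  df <- data.frame(subject_id = feats$subject, label = feats$label,
                   feats$x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
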