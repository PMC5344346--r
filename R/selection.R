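# The two selection blocks: Wavelet-Level Selection explores every (mother
# wavelet, decomposition level) pair with features from all bands;
# Band-Feature Selection then exhaustively scores every non-empty pair of
# band and feature subsets for a chosen wavelet/level. Both rank candidate
# settings by pooled cross-validated accuracy on the same fixed folds.

# features of every band of the full cascade, computed once per wavelet:
# returns detail feature blocks for levels 1..max_level plus approximation
# blocks at each level, so any (level, band subset) slices this cache.
.cascade_features <- function(segments, wavelet, max_level,
                              features = feature_names(),
                              source_range = NULL) {
  flt <- wavelet_filters(wavelet)
  nfeat <- length(features)
  n <- length(segments)
  det <- lapply(seq_len(max_level), function(l) matrix(0, n, nfeat))
  app <- lapply(seq_len(max_level), function(l) matrix(0, n, nfeat))
  for (i in seq_len(n)) {
    cur <- segments[[i]]$samples
    for (l in seq_len(max_level)) {
      step <- .dwt_step(cur, flt$dec_lo, flt$dec_hi)
      det[[l]][i, ] <- band_features(step$d, features)
      app[[l]][i, ] <- band_features(step$a, features)
      cur <- step$a
    }
  }
  for (l in seq_len(max_level)) {
    colnames(det[[l]]) <- paste0("b", l, "_", features)
    colnames(app[[l]]) <- paste0("b", l + 1L, "_", features)
  }
  list(detail = det, approx = app, features = features)
}

# all-bands feature matrix at a given level from the cascade cache
.level_matrix <- function(cache, level) {
  do.call(cbind, c(cache$detail[seq_len(level)], list(cache$approx[[level]])))
}

#' Wavelet-Level Selection: search mother wavelets and decomposition levels
#'
#' For every candidate mother wavelet and every decomposition level from 1 to
#' the wavelet's maximum for this segment length, builds feature vectors from
#' all bands and all requested features, runs the cross-validation scheme
#' with an RBF-SVM, and records the pooled confusion metrics. Folds are
#' constructed once and reused across all (wavelet, level) pairs so that
#' every setting is scored on identical train/test splits.
#'
#' @param segments list of equal-length [eeg_segment]s with both classes.
#' @param wavelets character vector of catalog member names; the full
#'   54-wavelet catalog by default.
#' @param scheme a [cv_scheme()].
#' @param config a [classifier_config()].
#' @param max_level optional cap on the deepest level searched (level range
#'   is `1..min(max_level, theoretical max)` per wavelet).
#' @param features feature set used during this stage (all nine by default).
#' @param source_range passed to the band-frequency bookkeeping.
#' @param verbose print one line per wavelet.
#' @return An object of class `wavelet_level_result`: list with `entries`
#'   (data.frame: wavelet, family, level, max_level, dimension, TP, FP, TN,
#'   FN, accuracy, sensitivity, specificity, ppv, npv), `best_per_wavelet`,
#'   `best_per_family` (from [pick_family_best_max()]), and the call
#'   settings.
#' @export
wavelet_level_search <- function(segments,
                                 wavelets = wavelet_catalog()$wavelet,
                                 scheme = cv_scheme("loso"),
                                 config = classifier_config(),
                                 max_level = NULL,
                                 features = feature_names(),
                                 source_range = NULL,
                                 verbose = FALSE) {
  stopifnot(is.list(segments), length(segments) > 1L, length(wavelets) > 0L)
  labels <- vapply(segments, `[[`, "", "label")
  subjects <- vapply(segments, `[[`, "", "subject_id")
  if (length(unique(labels)) < 2L) stop("segments must contain both classes")
  n_samples <- unique(vapply(segments, function(s) length(s$samples), 1L))
  if (length(n_samples) != 1L) stop("segments must have equal length")
  features <- .check_features(features)
  folds <- .make_folds(labels, subjects, scheme)

  cat54 <- wavelet_catalog()
  unknown <- setdiff(wavelets, cat54$wavelet)
  if (length(unknown)) stop("unknown wavelet(s): ", paste(unknown, collapse = ", "))

  entries <- list()
  for (w in wavelets) {
    f_len <- cat54$filter_length[match(w, cat54$wavelet)]
    w_max <- max_decomposition_level(n_samples, f_len)
    if (!is.null(max_level)) w_max <- min(w_max, as.integer(max_level))
    cache <- .cascade_features(segments, w, w_max, features, source_range)
    for (lev in seq_len(w_max)) {
      x <- .level_matrix(cache, lev)
      m <- .run_cv(x, labels, folds, config)
      entries[[length(entries) + 1L]] <- data.frame(
        wavelet = w, family = cat54$family[match(w, cat54$wavelet)],
        level = lev, max_level = w_max, dimension = ncol(x),
        TP = m$TP, FP = m$FP, TN = m$TN, FN = m$FN,
        accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity, ppv = m$ppv, npv = m$npv
      )
    }
    if (verbose) {
      last <- do.call(rbind, entries)
      best <- last[last$wavelet == w, ]
      best <- best[which.max(best$accuracy), ]
      message(sprintf("%s: max level %d, best %.4f at level %d",
                      w, w_max, best$accuracy, best$level))
    }
  }
  entries <- do.call(rbind, entries)
  res <- structure(
    list(entries = entries, scheme = scheme, config = config,
         features = features, n_segments = length(segments)),
    class = "wavelet_level_result"
  )
  res$best_per_wavelet <- .best_per(res$entries, "wavelet")
  res$best_per_family <- pick_family_best_max(res)
  res
}

# argmax accuracy within groups; ties -> lower level, shorter filter, name
.best_per <- function(entries, group) {
  cat54 <- wavelet_catalog()
  entries$filter_length <- cat54$filter_length[match(entries$wavelet, cat54$wavelet)]
  split_rows <- split(entries, entries[[group]])
  out <- do.call(rbind, lapply(split_rows, function(df) {
    df <- df[order(-df$accuracy, df$level, df$filter_length, df$wavelet), ]
    df[1L, ]
  }))
  rownames(out) <- NULL
  out[order(out[[group]]), setdiff(names(out), "filter_length")]
}

#' Best member per family by maximal accuracy
#'
#' Per wavelet family, retains the (wavelet, level) entry with the highest
#' cross-validated accuracy. Ties are broken toward the lower decomposition
#' level, then the shorter filter, then lexicographic name — i.e. toward the
#' computationally cheaper setting.
#'
#' @param result a `wavelet_level_result`.
#' @return data.frame with one row per family.
#' @export
pick_family_best_max <- function(result) {
  stopifnot(inherits(result, "wavelet_level_result"))
  .best_per(result$entries, "family")
}

#' Best member per family by an accuracy threshold
#'
#' Per family, among entries reaching `threshold` accuracy, picks the lowest
#' decomposition level and, within that level, the smallest vanishing-moment
#' count (the "simplest sufficient" rule used when many settings classify
#' nearly perfectly). Families with no entry at the threshold fall back to
#' the maximal-accuracy rule, with a message.
#'
#' @param result a `wavelet_level_result`.
#' @param threshold accuracy threshold in (0, 1).
#' @return data.frame with one row per family.
#' @export
pick_family_best_threshold <- function(result, threshold = 0.95) {
  stopifnot(inherits(result, "wavelet_level_result"),
            threshold > 0, threshold < 1)
  cat54 <- wavelet_catalog()
  entries <- result$entries
  entries$vm <- cat54$vanishing_moments[match(entries$wavelet, cat54$wavelet)]
  entries$vm[is.na(entries$vm)] <- Inf   # dmey: no finite vanishing moments
  fallback <- pick_family_best_max(result)
  out <- do.call(rbind, lapply(split(entries, entries$family), function(df) {
    ok <- df[df$accuracy >= threshold, , drop = FALSE]
    if (nrow(ok) == 0L) {
      fam <- df$family[1L]
      message("family '", fam, "': no entry reached accuracy ", threshold,
              "; falling back to the maximal-accuracy rule")
      return(cbind(fallback[fallback$family == fam, ], vm = NA))
    }
    ok <- ok[order(ok$level, ok$vm, ok$wavelet), ]
    ok[1L, ]
  }))
  rownames(out) <- NULL
  out[order(out$family), setdiff(names(out), "vm")]
}

#' @export
print.wavelet_level_result <- function(x, ...) {
  cat(sprintf("<wavelet_level_result> %d (wavelet, level) settings on %d segments (%s CV)\n",
              nrow(x$entries), x$n_segments, x$scheme$type))
  cat("Best per family:\n")
  print(x$best_per_family[, c("family", "wavelet", "level", "accuracy")],
        row.names = FALSE)
  invisible(x)
}

#' Number of band/feature subset combinations
#'
#' A level-`j` decomposition has `j + 1` bands; with `m` features per band
#' the exhaustive search scores every non-empty subset pair:
#' `(2^(j+1) - 1) * (2^m - 1)` combinations.
#'
#' @param j decomposition level (>= 1).
#' @param m number of candidate features (>= 1).
#' @return Count as a double (exact for the sizes involved).
#' @export
#' @examples
#' count_combinations(7, 9) # 130305
count_combinations <- function(j, m) {
  stopifnot(j >= 1, m >= 1)
  (2^(j + 1) - 1) * (2^m - 1)
}

#' Percent reduction of the feature-vector dimension
#'
#' Relative to the full representation of `(j + 1) * m` values (all bands,
#' all features), a selection of `n_bands_selected * n_features_selected`
#' values reduces the dimension by
#' `100 * (1 - nb * nf / ((j + 1) * m))` percent, reported to 2 decimals.
#'
#' @param j decomposition level.
#' @param n_bands_selected number of selected bands (1..j+1).
#' @param n_features_selected number of selected features (1..m).
#' @param m number of candidate features per band.
#' @return Percentage, rounded to 2 decimals.
#' @export
#' @examples
#' dimensionality_reduction(8, 8, 3) # 70.37
dimensionality_reduction <- function(j, n_bands_selected, n_features_selected,
                                     m = 9L) {
  stopifnot(n_bands_selected >= 1, n_bands_selected <= j + 1,
            n_features_selected >= 1, n_features_selected <= m)
  round(100 * (1 - (n_bands_selected * n_features_selected) / ((j + 1) * m)), 2)
}

# non-empty subsets of a vector, ordered by increasing size then
# lexicographically by element order — deterministic and tie-break friendly
.subsets <- function(x) {
  n <- length(x)
  out <- list()
  for (size in seq_len(n)) {
    combn_idx <- utils::combn(n, size)
    for (col in seq_len(ncol(combn_idx))) {
      out[[length(out) + 1L]] <- x[combn_idx[, col]]
    }
  }
  out
}

#' Band-Feature Selection: exhaustive subset search
#'
#' For a fixed wavelet and decomposition level, evaluates the cross-validated
#' accuracy of every non-empty pair (band subset, feature subset) drawn from
#' the candidate sets, and reports the winning combination. The DWT and the
#' per-band features are computed once per segment; each combination slices
#' the cached matrix. All combinations are scored on the same folds. The
#' winner maximizes accuracy; ties are broken toward the smaller dimension
#' (fewer values to compute), then lexicographically by band and feature
#' subset. Restricting `candidate_bands`/`candidate_features` implements the
#' clinically guided narrowed search (e.g. bands covering the rhythms a
#' pathology implicates).
#'
#' @param segments list of equal-length [eeg_segment]s.
#' @param wavelet catalog member name.
#' @param level decomposition level (`<=` the wavelet's maximum here).
#' @param scheme a [cv_scheme()].
#' @param config a [classifier_config()].
#' @param candidate_bands integer band indices searched (default all
#'   `1..level+1`).
#' @param candidate_features character feature names searched (default all
#'   nine).
#' @param source_range passed to [decompose()].
#' @param verbose print progress every 50 combinations.
#' @return An object of class `band_feature_result`: list with `entries`
#'   (data.frame: bands, features, n_bands, n_features, dimension, TP..npv),
#'   `best` (row index, band subset, feature subset, metrics),
#'   `dimensionality_reduction` (percent, relative to all `level+1` bands and
#'   9 features), and the call settings.
#' @export
band_feature_search <- function(segments, wavelet, level,
                                scheme = cv_scheme("loso"),
                                config = classifier_config(),
                                candidate_bands = NULL,
                                candidate_features = NULL,
                                source_range = NULL,
                                verbose = FALSE) {
  stopifnot(is.list(segments), length(segments) > 1L)
  level <- as.integer(level)
  n_bands <- level + 1L
  if (is.null(candidate_bands)) candidate_bands <- seq_len(n_bands)
  candidate_bands <- sort(unique(as.integer(candidate_bands)))
  if (length(candidate_bands) == 0L) stop("candidate band set must be non-empty")
  if (any(candidate_bands < 1L | candidate_bands > n_bands)) {
    stop("candidate bands must be in 1..", n_bands)
  }
  if (is.null(candidate_features)) candidate_features <- feature_names()
  candidate_features <- .check_features(candidate_features)

  labels <- vapply(segments, `[[`, "", "label")
  subjects <- vapply(segments, `[[`, "", "subject_id")
  folds <- .make_folds(labels, subjects, scheme)

  # cache: full matrix over candidate bands x all candidate features
  feats <- segment_features(segments, wavelet, level,
                            band_subset = candidate_bands,
                            features = candidate_features,
                            source_range = source_range)
  band_sets <- .subsets(candidate_bands)
  feat_sets <- .subsets(candidate_features)

  n_comb <- length(band_sets) * length(feat_sets)
  rows <- vector("list", n_comb)
  i <- 0L
  for (bs in band_sets) {
    for (fs in feat_sets) {
      i <- i + 1L
      cols <- as.vector(outer(fs, bs, function(f, b) paste0("b", b, "_", f)))
      m <- .run_cv(feats$x[, cols, drop = FALSE], labels, folds, config)
      rows[[i]] <- data.frame(
        bands = paste(bs, collapse = ","),
        features = paste(fs, collapse = ","),
        n_bands = length(bs), n_features = length(fs),
        dimension = length(cols),
        TP = m$TP, FP = m$FP, TN = m$TN, FN = m$FN,
        accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity, ppv = m$ppv, npv = m$npv
      )
      if (verbose && i %% 50L == 0L) {
        message(i, "/", n_comb, " combinations scored")
      }
    }
  }
  entries <- do.call(rbind, rows)
  ord <- order(-entries$accuracy, entries$dimension,
               entries$bands, entries$features)
  best_row <- ord[1L]
  best <- list(
    row = best_row,
    band_subset = as.integer(strsplit(entries$bands[best_row], ",")[[1]]),
    feature_subset = strsplit(entries$features[best_row], ",")[[1]],
    metrics = confusion_metrics(entries$TP[best_row], entries$FP[best_row],
                                entries$TN[best_row], entries$FN[best_row]),
    dimension = entries$dimension[best_row]
  )
  structure(
    list(wavelet = wavelet, level = level, entries = entries, best = best,
         dimensionality_reduction = dimensionality_reduction(
           level, entries$n_bands[best_row],
           entries$n_features[best_row], m = 9L),
         scheme = scheme, config = config,
         candidate_bands = candidate_bands,
         candidate_features = candidate_features),
    class = "band_feature_result"
  )
}

#' @export
print.band_feature_result <- function(x, ...) {
  cat(sprintf("<band_feature_result> %s level %d: %d combinations scored\n",
              x$wavelet, x$level, nrow(x$entries)))
  cat(sprintf("  best: bands {%s} x features {%s} (dimension %d)\n",
              paste(x$best$band_subset, collapse = ","),
              paste(x$best$feature_subset, collapse = ","),
              x$best$dimension))
  cat(sprintf("  accuracy %.4f, dimensionality reduction %.2f%%\n",
              x$best$metrics$accuracy, x$dimensionality_reduction))
  invisible(x)
}
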