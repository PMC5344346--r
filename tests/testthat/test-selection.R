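# helper: wrap a hand-written entries table as a wavelet_level_result
fake_wl_result <- function(entries) {
  structure(list(entries = entries, n_segments = 0L,
                 scheme = cv_scheme("loso")),
            class = "wavelet_level_result")
}

test_that("combination counts match brute-force subset enumeration", {
  for (j in 1:4) {
    for (m in 1:4) {
      n_bands <- length(dwtselect:::.subsets(seq_len(j + 1)))
      n_feats <- length(dwtselect:::.subsets(seq_len(m)))
      expect_equal(count_combinations(j, m), n_bands * n_feats)
    }
  }
  expect_equal(count_combinations(1, 1), 3)
  expect_equal(count_combinations(2, 2), 21)
  expect_equal(count_combinations(7, 9), 130305)
})

test_that("family winner by maximum accuracy breaks ties toward simplicity", {
  entries <- data.frame(
    wavelet = c("db1", "db2", "db3"), family = "db",
    level = c(3, 5, 2), max_level = 6, dimension = 1,
    TP = 9, FP = 1, TN = 9, FN = 1,
    accuracy = c(0.90, 0.90, 0.88),
    sensitivity = 0.9, specificity = 0.9, ppv = 0.9, npv = 0.9
  )
  best <- pick_family_best_max(fake_wl_result(entries))
  expect_equal(best$wavelet, "db1")               # tie: lower level wins
  expect_equal(best$level, 3)

  entries$accuracy <- c(0.88, 0.92, 0.88)
  best2 <- pick_family_best_max(fake_wl_result(entries))
  expect_equal(best2$wavelet, "db2")              # plain argmax
  single <- entries[1, ]
  expect_equal(pick_family_best_max(fake_wl_result(single))$wavelet, "db1")
  # equal accuracy and level: shorter filter wins (db1 has 2 taps, db2 has 4)
  entries2 <- entries; entries2$accuracy <- 0.9; entries2$level <- 3
  expect_equal(pick_family_best_max(fake_wl_result(entries2))$wavelet, "db1")
})

test_that("threshold rule picks lowest level then smallest vanishing moments", {
  entries <- data.frame(
    wavelet = c("sym2", "sym5"), family = "sym",
    level = c(1, 1), max_level = 10, dimension = 1,
    TP = 9, FP = 1, TN = 9, FN = 1,
    accuracy = c(0.957, 0.97),
    sensitivity = 0.9, specificity = 0.9, ppv = 0.9, npv = 0.9
  )
  best <- pick_family_best_threshold(fake_wl_result(entries), 0.95)
  expect_equal(best$wavelet, "sym2")    # same level, fewer vanishing moments

  entries2 <- data.frame(
    wavelet = c("coif1", "coif2"), family = "coif",
    level = c(1, 2), max_level = 8, dimension = 1,
    TP = 9, FP = 1, TN = 9, FN = 1,
    accuracy = c(0.96, 0.99),
    sensitivity = 0.9, specificity = 0.9, ppv = 0.9, npv = 0.9
  )
  best2 <- pick_family_best_threshold(fake_wl_result(entries2), 0.95)
  expect_equal(best2$wavelet, "coif1")  # lower level beats higher accuracy

  # nothing reaches the threshold: fall back to the argmax rule, with a note
  entries3 <- entries2; entries3$accuracy <- c(0.6, 0.8)
  expect_message(
    best3 <- pick_family_best_threshold(fake_wl_result(entries3), 0.95),
    "falling back")
  expect_equal(best3$wavelet, "coif2")
})

test_that("dimensionality reduction reproduces the printed percentages", {
  expect_equal(dimensionality_reduction(8, 8, 3), 70.37)   # haar, level 8
  expect_equal(dimensionality_reduction(7, 6, 7), 41.67)   # coif3, level 7
  expect_equal(dimensionality_reduction(8, 8, 4), 60.49)   # rbio3.5
  expect_equal(dimensionality_reduction(8, 8, 8), 20.99)   # sym5
  expect_equal(dimensionality_reduction(1, 1, 5), 72.22)   # sym2, level 1
  expect_equal(dimensionality_reduction(1, 1, 4), 77.78)   # bior1.1
  expect_equal(dimensionality_reduction(2, 2, 5), 62.96)   # dmey, level 2
  expect_error(dimensionality_reduction(1, 5, 1))
})

test_that("a one-wavelet one-level search reduces to a single CV run", {
  segs <- generate_dataset(tiny_config())
  wl <- wavelet_level_search(segs, "db2", scheme = cv_scheme("loso"),
                             max_level = 1)
  expect_equal(nrow(wl$entries), 1L)
  direct <- leave_one_subject_out_cv(segs, function(s)
    segment_features(s, "db2", 1)$x)
  expect_equal(wl$entries$accuracy, direct$accuracy)
  expect_equal(wl$entries$TP, direct$TP)
  expect_equal(wl$entries$dimension, 18)           # 2 bands x 9 features
  expect_equal(wl$best_per_family$wavelet, "db2")
})

test_that("deeper levels win when the planted rhythm needs isolating", {
  # white background + a weak 2.5-3.5 Hz effect: at level 1 the effect is
  # diluted across the whole approximation band, by level 5 it is isolated
  accs <- sapply(1:10, function(seed) {
    cfg <- synthetic_config(n_subjects = 5, segments_per_class = 10,
                            sampling_rate = 128, window_seconds = 8,
                            background_exponent = 0,
                            effect_bands = data.frame(lo = 2.5, hi = 3.5,
                                                      gain = 1.5),
                            seed = seed)
    wl <- wavelet_level_search(generate_dataset(cfg), "haar",
                               scheme = cv_scheme("loso"), max_level = 5)
    wl$entries$accuracy
  })
  expect_gt(mean(accs[5, ] - accs[1, ]), 0)        # paired over 10 seeds
  expect_gte(sum(accs[5, ] > accs[1, ]), 8)
})

test_that("label-shuffled data stays at chance level", {
  cfg <- tiny_config(seed = 5)
  segs <- generate_dataset(cfg)
  set.seed(99)
  labs <- sample(vapply(segs, `[[`, "", "label"))
  segs <- Map(function(s, l) { s$label <- l; s }, segs, labs)
  wl <- wavelet_level_search(segs, "haar", scheme = cv_scheme("loso"),
                             max_level = 4)
  n <- length(segs)
  band99 <- 2.576 * sqrt(0.25 / n)
  expect_lt(max(wl$entries$accuracy), 0.5 + band99 + 1e-9)
  expect_gt(min(wl$entries$accuracy), 0.5 - band99 - 1e-9)
})

test_that("band-feature search is exhaustive, cached and dominant", {
  segs <- generate_dataset(tiny_config(seed = 2))
  bf <- band_feature_search(segs, "haar", 2,
                            candidate_bands = c(2, 3),
                            candidate_features = c("STD", "Energy"))
  expect_equal(nrow(bf$entries), 9L)               # 3 subsets x 3 subsets
  expect_equal(nrow(bf$entries), count_combinations(1, 2))

  # all bands as candidates: the winner dominates the everything-entry
  bf_full <- band_feature_search(segs, "haar", 2,
                                 candidate_features = c("Max", "STD", "Energy"))
  expect_equal(nrow(bf_full$entries), count_combinations(2, 3))
  full_row <- bf_full$entries[bf_full$entries$n_bands == 3 &
                                bf_full$entries$n_features == 3, ]
  expect_equal(nrow(full_row), 1L)
  expect_gte(bf_full$best$metrics$accuracy, full_row$accuracy)
  expect_true(all(bf_full$best$metrics$accuracy >= bf_full$entries$accuracy))

  # determinism: identical inputs give identical winners
  bf2 <- band_feature_search(segs, "haar", 2,
                             candidate_bands = c(2, 3),
                             candidate_features = c("STD", "Energy"))
  expect_identical(bf$entries, bf2$entries)
  expect_identical(bf$best, bf2$best)

  expect_error(band_feature_search(segs, "haar", 2, candidate_bands = 7),
               "candidate bands")
  expect_error(band_feature_search(segs, "haar", 2,
                                   candidate_bands = integer(0)),
               "non-empty")
})

test_that("winners report the dimensionality reduction of their subsets", {
  segs <- generate_dataset(tiny_config(seed = 4))
  bf <- band_feature_search(segs, "haar", 2,
                            candidate_bands = c(2, 3),
                            candidate_features = c("STD", "Energy"))
  nb <- bf$entries$n_bands[bf$best$row]
  nf <- bf$entries$n_features[bf$best$row]
  expect_equal(bf$dimensionality_reduction,
               dimensionality_reduction(2, nb, nf, m = 9))
})
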