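# Single-step coefficients are checked against reference values computed
# with an independent DWT implementation (PyWavelets 1.9, mode "symmetric")
# on a fixed 16-sample signal, frozen here.
ref_x <- c(0.841470984807897, 1.81859485365136, 0.423360024179602,
           -3.02720998123171, -0.958924274663138, -0.558830996397852,
           1.97095979615637, 3.95743298649353, 0.412118485241757,
           -1.08804222177874, -2.99997061965211, -2.14629167200174,
           0.420167036826641, 1.98121471138974, 1.95086352047135,
           -1.15161326666026)
ref_coefs <- list(
  haar = list(
    a = c(1.88095059277722, -1.84119996182385, -1.07321504434885,
          4.19200673814913, -0.47795025767025, -3.63895696419306,
          1.69803331838141, 0.56515527433489),
    d = c(-0.69093091371845, 2.43992144978524, -0.282908670168541,
          -1.40464866353268, 1.0607738088038, -0.603642172839773,
          -1.10382739643906, 2.19378237465462)),
  db4 = list(
    a = c(-3.04167245730122, 0.673709957454277, 1.30230671257572,
          2.03066467065687, -2.87728987686729, 0.325763256163488,
          4.06119292392128, -2.45653081926292, -2.4747017980425,
          3.11230518597755, -1.55129652790802),
    d = c(-0.375926059908452, 0.0608069828030769, 1.66037007557674,
          0.254764214555426, -2.04559910738321, -0.145665434176539,
          0.940120840285291, -0.0643376508957811, -0.114841238449216,
          -0.103893846146771, -0.817103253605065)),
  `bior3.5` = list(
    a = c(-4.56548269274142, 2.50831100692981, 0.75714981836717,
          2.50831100692981, -4.56548269274142, 1.78467739426597,
          4.81015822049003, -4.70617874448753, -1.80345887568836,
          4.70790835068472, -3.61937174606034, 4.70790835068472,
          -1.80345887568836),
    d = c(-1.2705026191771, 0.0560423706168712, 0, -0.0560423706168713,
          1.2705026191771, 0.472526778773884, -1.33942667631929,
          -0.561685858648689, 0.480512786004201, 0.261757978096149, 0,
          -0.261757978096149, -0.480512786004201))
)

test_that("single-step coefficients match the independent reference", {
  for (w in names(ref_coefs)) {
    flt <- wavelet_filters(w)
    st <- dwtselect:::.dwt_step(ref_x, flt$dec_lo, flt$dec_hi)
    expect_equal(st$a, ref_coefs[[w]]$a, tolerance = 1e-12)
    expect_equal(st$d, ref_coefs[[w]]$d, tolerance = 1e-12)
  }
})

test_that("a level-1 decomposition has one detail and one approximation band", {
  dec <- decompose(ref_x, "haar", 1, sampling_rate = 16)
  expect_length(dec$bands, 2L)
  expect_equal(vapply(dec$bands, `[[`, "", "kind"),
               c("detail", "approximation"))
  expect_error(decompose(ref_x, "haar", 99, sampling_rate = 16),
               "level must be in")
})

test_that("decomposition inverts to the input across families and depths", {
  set.seed(42)
  x <- rnorm(1024)
  for (w in c("haar", "db7", "sym5", "coif3", "bior2.6", "rbio3.5", "dmey")) {
    f <- wavelet_filters(w)$length
    lev <- max_decomposition_level(1024, f)
    dec <- decompose(x, w, lev, sampling_rate = 64)
    expect_lt(max(abs(reconstruct(dec) - x)) / max(abs(x)), 1e-8)
  }
})

test_that("coefficient counts roughly halve per level", {
  set.seed(7)
  x <- rnorm(2048)
  for (w in c("haar", "db6", "bior3.5")) {
    f <- wavelet_filters(w)$length
    dec <- decompose(x, w, 4, sampling_rate = 64)
    len_in <- 2048
    for (l in 1:4) {
      n_d <- length(dec$bands[[l]]$coefficients)
      expect_gte(n_d, len_in %/% 2)
      expect_lte(n_d, len_in %/% 2 + f)   # boundary-extension slack
      len_in <- n_d
    }
  }
})

test_that("a pure tone's energy concentrates in its nominal band", {
  fs <- 256; n <- 20 * fs
  # mid-band tones: 96 Hz in band 1 (64-128), 48 Hz in band 2 (32-64)
  cases <- list(list(w = "haar", freq = 96), list(w = "db10", freq = 48))
  for (cs in cases) {
    x <- sin(2 * pi * cs$freq * seq_len(n) / fs)
    dec <- decompose(x, cs$w, 3, sampling_rate = fs)
    energy <- vapply(dec$bands, function(b) sum(b$coefficients^2), 1.0)
    tab <- band_table(dec)
    target <- which(tab$freq_lo < cs$freq & cs$freq < tab$freq_hi)
    expect_gte(energy[target] / sum(energy), 0.8)
  }
})

test_that("band frequency mapping matches the dyadic tiling formulas", {
  f1 <- band_frequencies(0.5, 128, 1)
  expect_equal(f1$freq_lo, c(64.25, 0.5))
  expect_equal(f1$freq_hi, c(128, 64.25))
  f2 <- band_frequencies(0.5, 86.8, 2)
  expect_equal(f2$freq_lo, c(43.65, 22.075, 0.5))
  expect_equal(f2$freq_hi, c(86.8, 43.65, 22.075))
  expect_error(band_frequencies(5, 3, 1), "a < b")
})

test_that("band intervals tile the source range without gaps or overlaps", {
  set.seed(11)
  for (i in 1:200) {
    a <- runif(1, 0, 10); b <- a + runif(1, 0.5, 200)
    j <- sample(1:12, 1)
    f <- band_frequencies(a, b, j)
    expect_equal(sum(f$freq_hi - f$freq_lo), b - a, tolerance = 1e-9)
    # sorted by frequency, each hi meets the next lo
    o <- order(f$freq_lo)
    expect_equal(f$freq_lo[o][-1], f$freq_hi[o][-(j + 1)], tolerance = 1e-9)
    expect_equal(f$freq_lo[o][1], a)
    expect_equal(f$freq_hi[o][j + 1], b)
    # detail widths double going up in frequency
    d <- f[f$kind == "detail", ]
    w <- d$freq_hi - d$freq_lo
    if (j > 1) expect_equal(w[-j], 2 * w[-1], tolerance = 1e-9)
  }
})

test_that("rhythm overlap uses the conventional open ranges", {
  expect_equal(rhythm_overlap(c(64.25, 128)), "gamma")
  expect_equal(rhythm_overlap(c(2, 5)), c("delta", "theta"))
  expect_equal(rhythm_overlap(c(7.2, 7.9)), character(0))  # theta/alpha gap
  dec <- decompose(ref_x, "haar", 1, sampling_rate = 16)
  expect_type(rhythm_overlap(dec$bands[[1]]), "character")
})
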