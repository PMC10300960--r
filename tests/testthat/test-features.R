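test_that("energy summary matches brute-force sums and sums to 100%", {
  dec <- emd_decompose(make_tone(39), fs = 4800)
  es <- energy_summary(dec)
  expect_lt(abs(sum(es$imf_ratio) + es$residual_ratio - 100), 1e-6)

  set.seed(13)
  x <- stats::rnorm(960)
  dec <- emd_decompose(x, fs = 4800)
  es <- energy_summary(dec)
  brute_total <- sum(dec$imfs^2) + sum(dec$residual^2)
  expect_equal(es$e_total, brute_total)
  for (i in seq_len(dec$n_imfs)) {
    expect_equal(es$imf_ratio[i], 100 * sum(dec$imfs[, i]^2) / brute_total)
  }
  expect_lt(abs(sum(es$imf_ratio) + es$residual_ratio - 100), 1e-6)

  z <- energy_summary(emd_decompose(numeric(64), fs = 4800))
  expect_true(z$degenerate)
  expect_equal(z$e_total, 0)
})

test_that("competent-IMF selection ranks by average ratio with low-index ties", {
  ratios <- c(31.92, 25.09, 19.29, 12.14, 6.62, 1.90, 0.21)
  expect_equal(select_cimf(ratios, k = 2), c(1L, 2L))
  expect_equal(select_cimf(c(10, 10), k = 1), 1L)
  set.seed(4)
  for (rep in 1:20) {
    r <- stats::runif(7)
    expect_equal(select_cimf(r, k = 3), order(r, decreasing = TRUE)[1:3])
  }
  expect_error(select_cimf(numeric(0)), "empty")
  expect_error(select_cimf(c(1, 2), k = 3), "exceeds")
})

test_that("ERD is the per-segment energy ratio of the chosen mode", {
  tone <- make_tone(39)
  decs <- list(emd_decompose(tone, fs = 4800),
               emd_decompose(numeric(960), fs = 4800))
  f <- feature_erd(decs, 1)
  expect_gt(f$values[1], 99) # tone mode carries nearly everything
  expect_equal(f$values[2], 0) # no modes at all
  expect_true(f$flags[2])
  f9 <- feature_erd(decs, 9)
  expect_equal(f9$values, c(0, 0)) # index deeper than any decomposition
  expect_true(all(f9$flags))
})

test_that("ESD picks the tallest marginal bin inside the domain", {
  tone <- make_tone(39)
  decs <- list(emd_decompose(tone, fs = 4800))
  marg <- emdetect:::segment_marginals(decs, 1)
  f <- feature_esd(decs, 1, main_domain = c(1, 150))
  keep <- marg[[1]]$bins >= 1 & marg[[1]]$bins <= 150
  expect_equal(f$values[1], max(marg[[1]]$energy_ratio[keep]))
  # all mass outside the domain
  f_out <- feature_esd(decs, 1, main_domain = c(500, 600))
  expect_equal(f_out$values[1], 0)
  expect_error(feature_esd(decs, 1, main_domain = c(10, 10)), "empty")
})

test_that("ESED reproduces entropy closed forms", {
  # delta distribution: all mass in one bin, P = 1
  m_delta <- fake_marginal_at(39, 100)
  f <- feature_esed(list(), 1, marginals = list(m_delta))
  expect_equal(f$values, 0)
  # uniform over 4 bins, P = 0.25 each
  m_unif <- fake_marginal_at(10:13, rep(25, 4))
  f <- feature_esed(list(), 1, marginals = list(m_unif))
  expect_equal(f$values, log(4), tolerance = 1e-12)
  # {0.5, 0.25, 0.25}
  m_mix <- fake_marginal_at(5:7, c(50, 25, 25))
  f <- feature_esed(list(), 1, marginals = list(m_mix))
  expect_equal(f$values, entropy_direct(c(0.5, 0.25, 0.25)),
               tolerance = 1e-12)
  expect_equal(f$values, 1.0397, tolerance = 1e-4)
})

test_that("ESED uses the literal total-energy normalization over the range", {
  # half the energy lies outside the range: in-range P sums to 0.5
  m <- fake_marginal_at(c(10, 11, 500), c(25, 25, 50))
  f <- feature_esed(list(), 1, freq_range = c(1, 100), marginals = list(m))
  expect_equal(f$values, entropy_direct(c(0.25, 0.25)), tolerance = 1e-12)
  # entropy never exceeds log of the bin count of the range
  set.seed(6)
  for (rep in 1:20) {
    e <- stats::runif(30)
    e <- 100 * e / sum(e)
    m <- fake_marginal_at(1:30, e)
    f <- feature_esed(list(), 1, freq_range = c(1, 30),
                      marginals = list(m))
    expect_lte(f$values, log(30) + 1e-12)
  }
})

test_that("CESED reproduces its hand-worked cases and degenerate rule", {
  # domain energies {0, 1}: S = {0, 1}, P = {0, 1}, H = 0
  m <- fake_marginal_at(c(10, 11), c(0, 1))
  f <- feature_cesed(list(), 1, main_domain = c(10, 11),
                     marginals = list(m))
  expect_equal(f$values, 0)
  # {0, 1, 1}: S = {0, 1, 1}, P = {0, .5, .5}, H = log 2
  m <- fake_marginal_at(10:12, c(0, 1, 1))
  f <- feature_cesed(list(), 1, main_domain = c(10, 12),
                     marginals = list(m))
  expect_equal(f$values, log(2), tolerance = 1e-12)
  # flat spectrum: no shape information
  m <- fake_marginal_at(10:12, c(2, 2, 2))
  f <- feature_cesed(list(), 1, main_domain = c(10, 12),
                     marginals = list(m))
  expect_equal(f$values, 0)
  expect_true(f$flags[1])
})

test_that("CESED is invariant to affine rescaling of domain energies", {
  set.seed(8)
  for (rep in 1:10) {
    e <- stats::runif(40, 0, 5)
    alpha <- stats::runif(1, 0.1, 10)
    beta <- stats::runif(1, 0, 3)
    f1 <- feature_cesed(list(), 1, main_domain = c(1, 40),
                        marginals = list(fake_marginal_at(1:40, e)))
    f2 <- feature_cesed(list(), 1, main_domain = c(1, 40),
                        marginals = list(fake_marginal_at(1:40,
                                                          alpha * e + beta)))
    expect_equal(f1$values, f2$values, tolerance = 1e-9)
    expect_lte(f1$values, log(40) + 1e-12)
  }
})

test_that("feature table computes the requested algorithms consistently", {
  lr <- synth_generate(small_synth(seed = 2, dur = 10))
  segs <- segment_recording(lr$recording, 200)
  decs <- lapply(segs, emd_decompose)
  tab <- feature_table(decs, 1, main_domain = c(1, 100))
  expect_named(tab, c("erd", "esd", "esed", "cesed"))
  expect_length(tab$cesed$values, length(segs))
  only <- feature_table(decs, 1, algorithms = "cesed",
                        main_domain = c(1, 100))
  expect_named(only, "cesed")
  expect_equal(only$cesed$values, tab$cesed$values)
})

test_that("ERD on the call-band mode is elevated in call segments", {
  lr <- synth_generate(small_synth(seed = 5, dur = 20, noise_sd = 0.1))
  segs <- segment_recording(lr$recording, 200)
  decs <- lapply(segs, emd_decompose)
  cimf <- select_cimf(average_energy_ratios(decs), 1)
  f <- feature_erd(decs, cimf)
  expect_gt(mean(f$values[lr$labels == 1]), mean(f$values[lr$labels == 0]))
})

test_that("feature CSVs round-trip", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  lr <- synth_generate(small_synth(seed = 3, dur = 5))
  decs <- lapply(segment_recording(lr$recording, 200), emd_decompose)
  tab <- feature_table(decs, 1, main_domain = c(1, 100))
  write_features(tab, tmp, start_times = (seq_len(25) - 1) * 0.2)
  back <- read_features(tmp)
  expect_named(back, names(tab))
  for (a in names(tab)) expect_equal(back[[a]]$values, tab[[a]]$values)
  writeLines("segment,foo\n1,2", tmp)
  expect_error(read_features(tmp), "lacks")
})
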