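# Welch cross-spectra, MSC, phase, bands, AR(1) surrogates, partial
# coherence.

test_that("Welch auto-spectra are correctly scaled and located", {
  withr::with_seed(1, x <- rnorm(10000))
  sm <- cross_spectra(matrix(x, dimnames = list(NULL, "x")), fs = 1,
                      working_rate = NULL)
  df <- diff(sm$freq)[1]
  # Parseval: one-sided integral of the PSD ~ series variance
  expect_equal(sum(Re(sm$P[, 1, 1])) * df, var(x), tolerance = 0.05)

  # a pure 0.2 Hz tone peaks in the bin nearest 0.2 Hz
  t <- 0:999
  tone <- cbind(s = sin(2 * pi * 0.2 * t))
  smt <- cross_spectra(tone, fs = 1, working_rate = NULL)
  expect_equal(smt$freq[which.max(Re(smt$P[, 1, 1]))], 36 / 178) # bin nearest 0.2

  # series shorter than one segment is an error
  expect_error(cross_spectra(matrix(rnorm(100), ncol = 1), fs = 1,
                             working_rate = NULL),
               class = "lcarousal_validation_error")
})

test_that("the spectral matrix is Hermitian with real non-negative diagonals", {
  d <- white_pair(1172, seed = 2)
  sm <- cross_spectra(d, fs = 1, working_rate = NULL)
  expect_equal(sm$P[, "a", "b"], Conj(sm$P[, "b", "a"]))
  expect_true(all(Re(sm$P[, "a", "a"]) >= 0))
  expect_true(all(abs(Im(sm$P[, "a", "a"]))
                  < 1e-12 * max(Re(sm$P[, "a", "a"]))))
})

test_that("MSC is bounded, symmetric, scale-invariant and 1 for self-pairs", {
  d <- white_pair(1172, seed = 3)
  d$a2 <- d$a
  sm <- cross_spectra(d, fs = 1, working_rate = NULL)
  m_ab <- msc(sm, "a", "b")
  expect_true(all(m_ab$msc >= 0 & m_ab$msc <= 1))
  expect_equal(m_ab$msc, msc(sm, "b", "a")$msc)
  expect_equal(msc(sm, "a", "a2")$msc, rep(1, 90), tolerance = 1e-9)

  # rescaling either series leaves MSC unchanged
  d_scaled <- dplyr::mutate(d, a = 7.3 * a)
  sm_s <- cross_spectra(d_scaled, fs = 1, working_rate = NULL)
  expect_equal(msc(sm_s, "a", "b")$msc, m_ab$msc, tolerance = 1e-10)

  expect_error(msc(sm, "a", "zz"), class = "lcarousal_validation_error")
})

test_that("MSC of independent noise matches the 1/K expectation", {
  # n chosen so the Welch segmentation yields K = 8 windows
  n <- 178 + 7 * 142
  means <- vapply(1:200, function(i) {
    d <- white_pair(n, seed = 400 + i)
    mean(msc(cross_spectra(d, fs = 1, working_rate = NULL), "a", "b")$msc)
  }, numeric(1))
  expect_equal(mean(means), 1 / 8, tolerance = 0.02 / 0.125)
})

test_that("phase lag has the stated sign convention and antisymmetry", {
  # B is A delayed by a quarter cycle of a 0.2 Hz tone: A leads, phase +pi/2
  t <- 0:999
  withr::with_seed(9, {
    d <- tibble::tibble(a = sin(2 * pi * 0.2 * t) + 0.05 * rnorm(1000),
                        b = sin(2 * pi * 0.2 * (t - 1.25)) + 0.05 * rnorm(1000))
  })
  sm <- cross_spectra(d, fs = 1, working_rate = NULL)
  ph <- phase_lag(sm, "a", "b")
  at02 <- which.min(abs(ph$frequency - 0.2))
  expect_equal(ph$phase[at02], pi / 2, tolerance = 0.1 / (pi / 2))
  expect_true(ph$reliable[at02])

  # antisymmetry at every bin
  ph_ba <- phase_lag(sm, "b", "a")
  wrap <- function(x) atan2(sin(x), cos(x))
  expect_equal(wrap(ph$phase + ph_ba$phase), rep(0, 90), tolerance = 1e-8)

  # identical series: zero phase
  d2 <- tibble::tibble(a = d$a, b = d$a)
  ph2 <- phase_lag(cross_spectra(d2, fs = 1, working_rate = NULL), "a", "b")
  expect_true(all(abs(ph2$phase) < 1e-8))
})

test_that("the band of maximum coherence summarises per-subject peaks", {
  # all subjects peak at exactly 0.2: degenerate CI
  prof <- purrr::map_dfr(1:6, function(s) {
    m <- rep(0.2, 90); m[37] <- 0.9
    tibble::tibble(subject = s, frequency = (0:89) / 178, msc = m)
  })
  band <- band_of_max_coherence(prof, n_boot = 200, seed = 1)
  expect_equal(band$median, 36 / 178)
  expect_equal(band$lower, band$upper)
  expect_equal(band$lower, 36 / 178)

  # the percentile CI contains the sample median
  withr::with_seed(31, {
    prof2 <- purrr::map_dfr(1:15, function(s) {
      m <- runif(90, 0, 0.3); m[sample(30:50, 1)] <- 0.9
      tibble::tibble(subject = s, frequency = (0:89) / 178, msc = m)
    })
  })
  b2 <- band_of_max_coherence(prof2, n_boot = 500, seed = 2)
  expect_gte(median(b2$peaks$peak), b2$lower)
  expect_lte(median(b2$peaks$peak), b2$upper)

  # flat profiles carry no peak information
  flat <- purrr::map_dfr(1:4, function(s)
    tibble::tibble(subject = s, frequency = (0:89) / 178, msc = 0.2))
  expect_error(band_of_max_coherence(flat, n_boot = 50),
               class = "lcarousal_validation_error")
})

test_that("synthetic coupling at 0.2 Hz is recovered by the band estimator", {
  cfg <- cohort_config(n_subjects = 1, series_length = 720, seed = 1)
  spec <- coupling_spec(band_center = 0.2, band_width = 0.05,
                        target_msc = 0.7, target_phase = 0)
  prof <- purrr::map_dfr(1:20, function(i) {
    d <- simulate_coupled_series(cfg, spec, seed = 600 + i)
    sm <- cross_spectra(d[, c("x", "y")], fs = 0.5, working_rate = 1)
    dplyr::mutate(msc(sm, "x", "y"), subject = i)
  })
  band <- band_of_max_coherence(prof, n_boot = 500, seed = 3, fmax = 0.25)
  expect_lt(abs(band$median - 0.2), 1.5 / 178)
})

test_that("band summaries reduce profiles to scalar point estimates", {
  prof <- tibble::tibble(frequency = (0:89) / 178, msc = 0.4,
                         phase = 0.7)
  bs <- band_summary(prof, c(0.1, 0.3))
  expect_equal(bs$median_msc, 0.4)
  expect_equal(bs$median_phase, 0.7)

  # single-bin band returns that bin
  prof2 <- tibble::tibble(frequency = (0:89) / 178,
                          msc = seq(0, 1, length.out = 90))
  one <- band_summary(prof2, c(20 / 178 - 1e-9, 20 / 178 + 1e-9))
  expect_equal(one$median_msc, prof2$msc[21])
  expect_equal(one$n_bins, 1)

  # a profile linear in frequency: the band median is the mid-bin value
  sel <- prof2$frequency >= 0.1 & prof2$frequency <= 0.3
  expect_equal(band_summary(prof2, c(0.1, 0.3))$median_msc,
               median(prof2$msc[sel]))

  expect_error(band_summary(prof2, c(0.9, 1.0)),
               class = "lcarousal_validation_error")
})

test_that("AR(1) fitting recovers known coefficients", {
  withr::with_seed(12, {
    w <- rnorm(2000)
    a8 <- as.numeric(arima.sim(list(ar = 0.8), 2000))
  })
  expect_lt(abs(fit_ar1(w)$coefficient), 0.05)
  expect_equal(fit_ar1(a8)$coefficient, 0.8, tolerance = 0.05 / 0.8)
  expect_error(fit_ar1(rep(1, 100)), class = "lcarousal_validation_error")
  expect_error(fit_ar1(rnorm(5)), "at least 10")
})

test_that("AR(1) surrogates match the source structure but not its phase", {
  withr::with_seed(13, x <- as.numeric(arima.sim(list(ar = 0.6), 2000)))
  s <- ar1_surrogate(x, seed = 5)
  expect_equal(length(s), length(x))
  expect_equal(fit_ar1(s)$coefficient, fit_ar1(x)$coefficient,
               tolerance = 0.1 / 0.6)
  expect_gt(var(s) / var(x), 0.9)
  expect_lt(var(s) / var(x), 1.1)
  # seeded reproducibility
  expect_identical(ar1_surrogate(x, seed = 5), s)
})

test_that("the surrogate null sits at the no-coherence level", {
  withr::with_seed(14, {
    x <- as.numeric(arima.sim(list(ar = 0.5), 1172))
    y <- as.numeric(arima.sim(list(ar = 0.5), 1172))
  })
  nl <- coherence_null(x, y, band = c(0.15, 0.25), n_surrogates = 150,
                       seed = 6, fs = 1, working_rate = NULL)
  expect_equal(nl$n_surrogates, 150)
  expect_true(all(nl$null >= 0 & nl$null <= 1))
  # K = 8 windows at this length: null mean near 1/K
  expect_equal(mean(nl$null), 1 / 8, tolerance = 0.04 / 0.125)
  # reproducible given the seed
  nl2 <- coherence_null(x, y, band = c(0.15, 0.25), n_surrogates = 150,
                        seed = 6, fs = 1, working_rate = NULL)
  expect_identical(nl$null, nl2$null)
  expect_error(coherence_null(x, y, c(0.15, 0.25), n_surrogates = 10),
               "at least 100")
})

test_that("partial coherence reduces to MSC and removes common drivers", {
  n <- 1172
  cfg <- cohort_config(n_subjects = 1, series_length = n,
                       sampling_interval = 1, seed = 5)
  # empty conditioning set: identical to ordinary MSC, bin-wise
  d <- simulate_coupled_series(cfg, coupling_spec(target_msc = 0.5), seed = 3)
  d$z <- withr::with_seed(77, as.numeric(arima.sim(list(ar = 0.3), n)))
  sm <- cross_spectra(d[, c("x", "y", "z")], fs = 1, working_rate = NULL)
  expect_equal(partial_coherence(sm, "x", "y")$msc, msc(sm, "x", "y")$msc,
               tolerance = 1e-10)

  # conditioning on an independent series barely changes the in-band MSC
  pc_ind <- partial_coherence(sm, "x", "y", "z")
  m_ord <- msc(sm, "x", "y")
  sel <- sm$freq >= 0.18 & sm$freq <= 0.22
  expect_lt(abs(mean(pc_ind$msc[sel]) - mean(m_ord$msc[sel])), 0.1)

  # a pure common driver: ordinary coherence high, partial collapses
  withr::with_seed(21, {
    z <- simulate_coupled_series(cfg, coupling_spec(target_msc = 1, noise_sd = 0),
                                 seed = 9)$x
    cd <- tibble::tibble(x = z + 0.3 * rnorm(n), y = z + 0.3 * rnorm(n), z = z)
  })
  sm2 <- cross_spectra(cd, fs = 1, working_rate = NULL)
  sel2 <- sm2$freq >= 0.18 & sm2$freq <= 0.22
  ord <- mean(msc(sm2, "x", "y")$msc[sel2])
  prt <- mean(partial_coherence(sm2, "x", "y", "z")$msc[sel2])
  expect_gt(ord, 0.6)
  expect_lt(prt, 0.3) # near the K-window null level once z is removed

  expect_error(partial_coherence(sm, "x", "y", "x"),
               class = "lcarousal_config_error")
})

test_that("observed band medians are tested against subject-matched nulls", {
  obs <- c(0.5, 0.52, 0.61, 0.55, 0.48, 0.59, 0.62, 0.51)
  expect_equal(partial_coherence_test(obs, obs)$p_value, 1)
  res <- partial_coherence_test(obs, obs - 0.2)
  # constant differences are fully tied: the tie-corrected maximal Z for
  # n = 8 is 17.5 / sqrt(51 - 10.5) = 2.7499; it is never below the
  # tie-free closed form (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24) = 2.4505
  expect_equal(res$statistic, 2.749861, tolerance = 1e-5)
  expect_gte(res$statistic, 2.450490)
  expect_lt(res$p_value, 0.02)
  # exact fallback below 5 subjects (distinct differences, all positive)
  res_small <- partial_coherence_test(c(0.42, 0.55, 0.61, 0.70),
                                      c(0.40, 0.50, 0.52, 0.60))
  expect_equal(res_small$method, "wilcoxon_exact")
  expect_equal(res_small$p_value, 0.125) # exact two-sided, V = 10, n = 4
})
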