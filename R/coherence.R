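# Spectral module: Welch cross-spectra, magnitude-squared coherence, phase
# lag, band of maximum coherence, AR(1) surrogate nulls, partial coherence.
#
# Estimation runs on a working grid resampled to 1 Hz by default: a
# 0-0.5 Hz / 90-bin analysis grid requires a Nyquist of 0.5 Hz, which BOLD
# sampled at TR = 2 s (Nyquist 0.25 Hz) cannot supply directly. Cubic-spline
# resampling to 1 Hz makes the grid well-defined; content above the original
# Nyquist is near zero and coherence there sits at the no-coherence floor.

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Cubic-spline resampling of an equidistant series onto a new rate.
resample_series <- function(x, fs_in, fs_out) {
  if (isTRUE(all.equal(fs_in, fs_out))) return(as.numeric(x))
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- seq(0, max(t_in), by = 1 / fs_out)
  splinefun(t_in, x, method = "fmm")(t_out)
}

# Windowed, detrended segment FFTs for a multichannel matrix.
# Returns list(F = array [n_freq, K, m], freq, U = window power, K).
welch_segment_fft <- function(X, fs, bins = 90, overlap = 0.2, detrend = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  nseg <- 2L * (bins - 1L)
  hop <- nseg - as.integer(round(overlap * nseg))
  if (n < nseg) {
    abort(sprintf("series too short for one segment (%d < %d samples)", n, nseg),
          class = "lcarousal_validation_error")
  }
  K <- (n - nseg) %/% hop + 1L
  w <- hamming_window(nseg)
  idx <- outer(seq_len(nseg), (0:(K - 1)) * hop, "+") # nseg x K
  segs <- matrix(0, nseg, K * m)
  for (j in seq_len(m)) {
    segs[, (j - 1) * K + seq_len(K)] <- matrix(X[as.vector(idx) + (j - 1) * n], nseg, K)
  }
  if (detrend) segs <- sweep(segs, 2, colMeans(segs))
  segs <- segs * w
  Fm <- stats::mvfft(segs)[seq_len(bins), , drop = FALSE]
  list(F = array(Fm, dim = c(bins, K, m)),
       freq = (0:(bins - 1)) * fs / nseg,
       U = sum(w^2), K = K, fs = fs, bins = bins)
}

# One-sided cross-spectral density between channels i and j from segment FFTs.
cross_density <- function(wf, i, j) {
  num <- rowSums(wf$F[, , i, drop = FALSE] * Conj(wf$F[, , j, drop = FALSE]))
  dim(num) <- NULL
  p <- num / (wf$K * wf$U * wf$fs)
  one_sided <- rep(2, wf$bins)
  one_sided[c(1, wf$bins)] <- 1 # DC and Nyquist are not doubled
  p * one_sided
}

#' Welch cross-spectral matrix of a set of equidistant series
#'
#' Welch-averaged cross-periodograms with Hamming tapers, 20\% segment
#' overlap and per-segment constant detrending. The segment length is
#' `2 * (bins - 1)` samples at the working rate so the one-sided grid has
#' exactly `bins` frequencies spanning `[0, working_rate/2]` (90 bins on
#' 0-0.5 Hz at the default 1 Hz working rate).
#'
#' @param data Data frame with an optional `time` column (s) and one numeric
#'   column per series, or a numeric matrix (then `fs` is required).
#' @param fs Sampling rate (Hz) of the input; inferred from `time` if absent.
#' @param bins One-sided frequency bins (90).
#' @param overlap Segment overlap fraction (0.2).
#' @param working_rate Resample inputs to this rate before estimation
#'   (1 Hz); `NULL` keeps the native rate.
#' @param detrend Subtract each segment's mean.
#' @return Object of class `spectral_matrix`: `freq` (Hz), `P` (complex
#'   array frequency x series x series, Hermitian per bin), `series`,
#'   `n_windows`, `fs`.
#' @export
cross_spectra <- function(data, fs = NULL, bins = 90, overlap = 0.2,
                          working_rate = 1, detrend = TRUE) {
  if (is.data.frame(data)) {
    if ("time" %in% names(data)) {
      tt <- data$time
      fs <- fs %||% (1 / median(diff(tt)))
      data <- data[setdiff(names(data), c("time", "subject", "stage"))]
    }
    X <- as.matrix(data)
  } else {
    X <- as.matrix(data)
  }
  assert_that(!is.null(fs), "sampling rate fs is required")
  assert_that(is.numeric(X) && ncol(X) >= 1, "need at least one numeric series")
  nm <- colnames(X) %||% paste0("series", seq_len(ncol(X)))
  rate <- working_rate %||% fs
  Xw <- do.call(cbind, lapply(seq_len(ncol(X)),
                              function(j) resample_series(X[, j], fs, rate)))
  wf <- welch_segment_fft(Xw, rate, bins = bins, overlap = overlap,
                          detrend = detrend)
  m <- ncol(Xw)
  P <- array(0i, dim = c(wf$bins, m, m), dimnames = list(NULL, nm, nm))
  for (i in seq_len(m)) {
    for (j in i:m) {
      pij <- cross_density(wf, i, j)
      P[, i, j] <- pij
      if (j > i) P[, j, i] <- Conj(pij)
    }
  }
  structure(list(freq = wf$freq, P = P, series = nm, n_windows = wf$K,
                 fs = rate, bins = wf$bins),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat("<spectral_matrix> ", length(x$series), "series,", x$bins, "bins on [0,",
      max(x$freq), "] Hz,", x$n_windows, "Welch windows\n")
  invisible(x)
}

check_pair <- function(sm, a, b) {
  missing <- setdiff(c(a, b), sm$series)
  if (length(missing) > 0) {
    abort(paste("series not in spectral matrix:", paste(missing, collapse = ", ")),
          class = "lcarousal_validation_error")
  }
}

#' Magnitude-squared coherence between two series
#'
#' `MSC(f) = |P_ab(f)|^2 / (P_aa(f) P_bb(f))`, clipped to `[0, 1]` against
#' rounding. Bins with zero auto-power are flagged undefined (NA).
#'
#' @param sm A [cross_spectra()] result.
#' @param a,b Series names.
#' @return Tibble of class `coh_profile`: `frequency`, `msc`.
#' @export
msc <- function(sm, a, b) {
  check_pair(sm, a, b)
  paa <- Re(sm$P[, a, a]); pbb <- Re(sm$P[, b, b])
  num <- Mod(sm$P[, a, b])^2
  denom <- paa * pbb
  vals <- ifelse(denom <= 0, NA_real_, pmin(pmax(num / denom, 0), 1))
  out <- tibble::tibble(frequency = sm$freq, msc = vals)
  class(out) <- c("coh_profile", class(out))
  out
}

#' Phase lag between two series per frequency bin
#'
#' The four-quadrant angle of the cross-spectrum, `atan2(Im P_ab, Re P_ab)`.
#' Sign convention: positive phase means the first series (`a`) leads.
#' Bins whose MSC falls below `msc_floor` are flagged unreliable (the
#' cross-power there is dominated by noise).
#'
#' @param sm A [cross_spectra()] result.
#' @param a,b Series names.
#' @param msc_floor Reliability floor on MSC (0.1).
#' @return Tibble: `frequency`, `phase` (radians, `(-pi, pi]`), `reliable`.
#' @export
phase_lag <- function(sm, a, b, msc_floor = 0.1) {
  check_pair(sm, a, b)
  pab <- sm$P[, a, b]
  ph <- atan2(Im(pab), Re(pab))
  m <- msc(sm, a, b)$msc
  tibble::tibble(frequency = sm$freq, phase = ph,
                 reliable = !is.na(m) & m >= msc_floor)
}

#' Combined coherence and phase profile for one pair
#'
#' @inheritParams phase_lag
#' @return Tibble of class `coh_profile`: `frequency`, `msc`, `phase`,
#'   `reliable`.
#' @export
coherence_profile <- function(sm, a, b, msc_floor = 0.1) {
  out <- dplyr::left_join(msc(sm, a, b), phase_lag(sm, a, b, msc_floor),
                          by = "frequency")
  class(out) <- c("coh_profile", class(out))
  out
}

#' Frequency band of maximum coherence across subjects
#'
#' Takes each subject's argmax frequency of MSC (ties resolved to the
#' lowest frequency) and returns the bootstrap percentile 95\% CI of the
#' median of these frequencies; the CI defines the band.
#'
#' @param profiles Tibble with `subject`, `frequency`, `msc` (stacked
#'   per-subject profiles).
#' @param n_boot Bootstrap resamples (5000).
#' @param seed Integer seed.
#' @param conf Confidence level (0.95).
#' @param fmin,fmax Optional frequency limits (Hz) for the peak search.
#'   Two principled restrictions: the search should stop at the native
#'   Nyquist when series are upsampled to the working grid (bins above it
#'   contain only interpolation images, which are coherent across channels
#'   because the underlying signal is shared), and a physiological prior
#'   such as the HF-HRV band (0.15-0.4 Hz) may bound where a
#'   parasympathetic coupling peak is sought.
#' @return List of class `max_coh_band`: `median`, `lower`, `upper`,
#'   `peaks` (per-subject argmax), `n_boot`.
#' @export
band_of_max_coherence <- function(profiles, n_boot = 5000, seed = 1,
                                  conf = 0.95, fmin = NULL, fmax = NULL) {
  assert_that(all(c("subject", "frequency", "msc") %in% names(profiles)),
              "profiles need subject, frequency, msc columns")
  if (!is.null(fmin)) profiles <- dplyr::filter(profiles, .data$frequency >= fmin)
  if (!is.null(fmax)) profiles <- dplyr::filter(profiles, .data$frequency <= fmax)
  peaks <- profiles |>
    dplyr::filter(!is.na(.data$msc)) |>
    dplyr::group_by(.data$subject) |>
    dplyr::arrange(.data$frequency, .by_group = TRUE) |>
    dplyr::summarise(flat = max(.data$msc) == min(.data$msc),
                     peak = .data$frequency[which.max(.data$msc)],
                     .groups = "drop")
  if (all(peaks$flat)) {
    abort("all coherence profiles are flat; no band of maximum coherence",
          class = "lcarousal_validation_error")
  }
  assert_that(nrow(peaks) >= 3, "need at least 3 subjects")
  pk <- peaks$peak
  boot_medians <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) median(sample(pk, length(pk), replace = TRUE)),
           numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot_medians, c(alpha, 1 - alpha)))
  structure(list(median = median(pk), lower = ci[1], upper = ci[2],
                 peaks = peaks[, c("subject", "peak")], n_boot = n_boot),
            class = "max_coh_band")
}

#' @export
print.max_coh_band <- function(x, ...) {
  cat(sprintf("<max_coh_band> median %.4f Hz, 95%% CI [%.4f, %.4f] (%d subjects, %d bootstrap resamples)\n",
              x$median, x$lower, x$upper, nrow(x$peaks), x$n_boot))
  invisible(x)
}

# Circular median: the observed angle minimizing the summed circular distance.
circular_median <- function(theta) {
  if (length(theta) == 0) return(NA_real_)
  cost <- vapply(theta, function(t0) {
    d <- abs(atan2(sin(theta - t0), cos(theta - t0)))
    sum(d)
  }, numeric(1))
  theta[which.min(cost)]
}

#' Band-median coherence (and phase) for a single profile
#'
#' The scalar point-estimate per subject/stage: median MSC (and circular
#' median phase, if present) over the bins inside the band.
#'
#' @param profile A [coherence_profile()] (or [msc()]) tibble.
#' @param band A [band_of_max_coherence()] result, or `c(lower, upper)` Hz.
#' @return Tibble: `median_msc`, `median_phase` (NA without phase), `n_bins`.
#' @export
band_summary <- function(profile, band) {
  rng <- if (inherits(band, "max_coh_band")) c(band$lower, band$upper) else band
  sel <- profile$frequency >= rng[1] & profile$frequency <= rng[2] &
    !is.na(profile$msc)
  if (!any(sel)) {
    abort("band does not overlap the frequency grid",
          class = "lcarousal_validation_error")
  }
  tibble::tibble(
    median_msc = median(profile$msc[sel]),
    median_phase = if ("phase" %in% names(profile))
      circular_median(profile$phase[sel]) else NA_real_,
    n_bins = sum(sel)
  )
}

#' Lag-1 Yule-Walker AR(1) fit
#'
#' @param x Numeric series (length >= 10, non-constant).
#' @return List: `coefficient` (clipped into (-1, 1) with a warning if
#'   needed), `innovation_variance`, `series_variance`, `n`.
#' @export
fit_ar1 <- function(x) {
  x <- as.numeric(x)
  assert_that(length(x) >= 10, "AR(1) fit needs at least 10 samples")
  if (sd(x) == 0) {
    abort("constant series: AR(1) coefficient undefined",
          class = "lcarousal_validation_error")
  }
  xc <- x - mean(x)
  phi <- sum(xc[-1] * xc[-length(xc)]) / sum(xc^2)
  if (abs(phi) >= 1) {
    warn("AR(1) coefficient clipped into (-1, 1)")
    phi <- sign(phi) * 0.999
  }
  v <- var(x)
  list(coefficient = phi, innovation_variance = v * (1 - phi^2),
       series_variance = v, n = length(x))
}

#' AR(1)-matched surrogate series
#'
#' A fresh realisation of the AR(1) process fitted to `x`, driven by new
#' white noise and variance-matched to the original -- independent of `x`
#' but sharing its lag-1 autocorrelation structure.
#'
#' @param x Numeric series.
#' @param seed Optional integer seed.
#' @return Numeric surrogate of the same length.
#' @export
ar1_surrogate <- function(x, seed = NULL) {
  fit <- fit_ar1(x)
  gen <- function() sim_ar1(length(x), fit$coefficient, sqrt(fit$series_variance))
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Surrogate null distribution of band-median coherence
#'
#' Fits AR(1) models to both series, draws `n_surrogates` independent
#' surrogate pairs with matched coefficients and variances, and computes the
#' band-median MSC for each pair -- the null distribution of the band
#' statistic under "no coupling beyond autocorrelation".
#'
#' @param x,y Numeric series on a common equidistant grid.
#' @param band `c(lower, upper)` Hz or a [band_of_max_coherence()].
#' @param n_surrogates Number of surrogate pairs (>= 100).
#' @param seed Integer seed.
#' @param fs Input sampling rate (Hz).
#' @param bins,overlap,working_rate Passed to the Welch estimator.
#' @return Object of class `surrogate_null`: `null` (numeric band-median
#'   MSC values), `ar_x`, `ar_y`, `band`, `n_surrogates`.
#' @export
coherence_null <- function(x, y, band, n_surrogates = 200, seed = 1,
                           fs = 1, bins = 90, overlap = 0.2,
                           working_rate = 1) {
  assert_that(n_surrogates >= 100, "need at least 100 surrogates")
  rng <- if (inherits(band, "max_coh_band")) c(band$lower, band$upper) else band
  rate <- working_rate %||% fs
  xw <- resample_series(x, fs, rate)
  yw <- resample_series(y, fs, rate)
  fx <- fit_ar1(xw); fy <- fit_ar1(yw)
  n <- length(xw)
  with_seed(seed, {
    S <- n_surrogates
    sx <- replicate(S, sim_ar1(n, fx$coefficient, sqrt(fx$series_variance)))
    sy <- replicate(S, sim_ar1(n, fy$coefficient, sqrt(fy$series_variance)))
    wf <- welch_segment_fft(cbind(sx, sy), rate, bins = bins, overlap = overlap)
    sel <- wf$freq >= rng[1] & wf$freq <= rng[2]
    assert_that(any(sel), "band does not overlap the frequency grid")
    null_vals <- vapply(seq_len(S), function(s) {
      fa <- wf$F[, , s, drop = FALSE]
      fb <- wf$F[, , S + s, drop = FALSE]
      num <- Mod(rowSums(fa * Conj(fb)))^2
      den <- rowSums(Mod(fa)^2) * rowSums(Mod(fb)^2)
      median(pmin(num[sel] / den[sel], 1))
    }, numeric(1))
    structure(list(null = null_vals, ar_x = fx$coefficient,
                   ar_y = fy$coefficient, band = rng,
                   n_surrogates = S),
              class = "surrogate_null")
  })
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf("<surrogate_null> %d surrogate pairs, AR(1) = (%.3f, %.3f), band [%.3f, %.3f] Hz, null mean %.3f\n",
              x$n_surrogates, x$ar_x, x$ar_y, x$band[1], x$band[2], mean(x$null)))
  invisible(x)
}

#' Partial coherence from the inverse spectral matrix
#'
#' Coherence between `a` and `b` after removing the linear influence of the
#' conditioning series: with `G(f) = P(f)^-1` over `{a, b} + conditioning`,
#' the partial coherence is `|G_ab|^2 / (G_aa G_bb)` per bin. With an empty
#' conditioning set this reduces exactly to the ordinary MSC. Near-singular
#' bins are ridge-regularised with a warning.
#'
#' @param sm A [cross_spectra()] result containing all needed series.
#' @param a,b The pair of interest.
#' @param conditioning Character vector of conditioning series (possibly
#'   empty).
#' @return Tibble of class `coh_profile`: `frequency`, `msc` (partial).
#' @export
partial_coherence <- function(sm, a, b, conditioning = character(0)) {
  check_pair(sm, a, b)
  missing <- setdiff(conditioning, sm$series)
  if (length(missing) > 0) {
    abort(paste("conditioning series not in spectral matrix:",
                paste(missing, collapse = ", ")),
          class = "lcarousal_validation_error")
  }
  assert_that(!any(c(a, b) %in% conditioning),
              "conditioning set must be disjoint from the pair")
  ids <- c(a, b, conditioning)
  nf <- length(sm$freq)
  vals <- numeric(nf)
  n_ridge <- 0L
  for (k in seq_len(nf)) {
    Pk <- sm$P[k, ids, ids]
    G <- tryCatch(solve(Pk), error = function(e) NULL)
    if (is.null(G) || any(!is.finite(Mod(G)))) {
      ridge <- 1e-8 * mean(Re(diag(Pk))) + 1e-300
      G <- solve(Pk + diag(ridge, nrow(Pk)))
      n_ridge <- n_ridge + 1L
    }
    denom <- Re(G[1, 1]) * Re(G[2, 2])
    vals[k] <- if (denom <= 0) NA_real_ else
      min(max(Mod(G[1, 2])^2 / denom, 0), 1)
  }
  if (n_ridge > 0) {
    warn(sprintf("%d singular bin(s) ridge-regularised in partial coherence", n_ridge))
  }
  out <- tibble::tibble(frequency = sm$freq, msc = vals)
  class(out) <- c("coh_profile", class(out))
  out
}

#' Paired test of observed band-median coherences against the surrogate null
#'
#' Wilcoxon signed-rank test of per-subject observed band medians against
#' their subject-matched null medians (normal approximation with tie and
#' continuity correction; exact distribution below 5 subjects).
#'
#' @param observed Numeric vector, one band-median per subject.
#' @param null_medians Matched numeric vector of per-subject null medians
#'   (e.g. median of each subject's [coherence_null()] distribution).
#' @return Tibble: `method`, `statistic`, `p_value`, `n`.
#' @export
partial_coherence_test <- function(observed, null_medians) {
  assert_that(length(observed) == length(null_medians),
              "observed and null values must be paired per subject")
  keep <- complete.cases(observed, null_medians)
  a <- observed[keep]; b <- null_medians[keep]
  if (length(a) < 5) {
    if (all(a == b)) {
      return(tibble::tibble(method = "wilcoxon_exact", statistic = 0,
                            p_value = 1, n = length(a)))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = TRUE))
    return(tibble::tibble(method = "wilcoxon_exact",
                          statistic = unname(wt$statistic),
                          p_value = wt$p.value, n = length(a)))
  }
  res <- signed_rank_z(a, b)
  tibble::tibble(method = "wilcoxon", statistic = res$statistic,
                 p_value = res$p, n = length(a))
}
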