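# Shared fixtures: small configs and hand-built tables used across tests.

tiny_config <- function(n_subjects = 6, series_length = 170, seed = 101) {
  cohort_config(n_subjects = n_subjects, series_length = series_length,
                sampling_interval = 2, seed = seed)
}

# Regular 1-second heartbeat over `n` seconds with optional extra beats
# (spurious) and dropped beats (gaps).
regular_beats <- function(n = 60, extra_at = numeric(0), drop_at = integer(0)) {
  t <- as.numeric(seq_len(n))
  if (length(drop_at) > 0) t <- t[-drop_at]
  sort(c(t, extra_at))
}

# Trial table with exact counts: one subject, `hits` of `n_old` old trials
# endorsed, `fa` of `n_new` new trials endorsed, `rec` correct names.
counts_trials <- function(hits, n_old, fa, n_new, rec = 0,
                          valence = "emotional", subject = "s01") {
  old <- tibble::tibble(
    subject = subject, valence = valence, is_old = TRUE,
    recognized = rep(c(TRUE, FALSE), c(hits, n_old - hits)),
    recollected_correct = c(rep(c(TRUE, FALSE), c(rec, hits - rec)),
                            rep(NA, n_old - hits))
  )
  new <- tibble::tibble(
    subject = subject, valence = valence, is_old = FALSE,
    recognized = rep(c(TRUE, FALSE), c(fa, n_new - fa)),
    recollected_correct = NA
  )
  dplyr::bind_rows(old, new)
}

# Two-channel white-noise frame long enough for K Welch windows at fs = 1.
white_pair <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(a = rnorm(n), b = rnorm(n)))
}

# Vectors with an exact sample correlation rho (Gram-Schmidt construction).
exact_cor_pair <- function(n, rho, seed = 99) {
  withr::with_seed(seed, {
    x <- rnorm(n); e <- rnorm(n)
    x <- scale(x)[, 1]
    e <- resid(lm(e ~ x)); e <- e / sd(e) * sd(x)
    list(x = x, y = rho * x + sqrt(1 - rho^2) * e)
  })
}
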