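# Behavioral module: recognition/recollection rates, equal-variance SDT
# indices, likelihood-ratio bias correction and the adjusted emotional
# memory score.

#' Chance level for the recollection phase
#'
#' With `n_options` name choices offered after an endorsed face, random
#' guessing yields a correct-name probability of `1/n_options`.
#'
#' @param n_options Number of name alternatives (3 in the task).
#' @return Chance accuracy in percent.
#' @export
recollection_chance_level <- function(n_options = 3) {
  assert_that(is_count(n_options), "n_options must be a positive integer")
  100 / n_options
}

#' Tabulate recognition counts per subject and valence
#'
#' @param trials Trial table: `subject`, `valence`, `is_old`, `recognized`,
#'   `recollected_correct` (NA unless the trial is old and endorsed).
#' @return Tibble per subject x valence: `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`, `recollected`, `n_old`, `n_new`.
#' @export
tabulate_counts <- function(trials) {
  required <- c("subject", "valence", "is_old", "recognized")
  assert_that(all(required %in% names(trials)),
              paste("trials must contain columns:", paste(required, collapse = ", ")))
  if (!"recollected_correct" %in% names(trials)) {
    trials$recollected_correct <- NA
  }
  bad <- which(!is.na(trials$recollected_correct) &
                 !(trials$is_old & trials$recognized))
  if (length(bad) > 0) {
    abort(paste0("recollection response without an endorsed old trial at row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "lcarousal_validation_error")
  }
  counts <- trials |>
    dplyr::group_by(.data$subject, .data$valence) |>
    dplyr::summarise(
      hits = sum(.data$is_old & .data$recognized),
      misses = sum(.data$is_old & !.data$recognized),
      false_alarms = sum(!.data$is_old & .data$recognized),
      correct_rejections = sum(!.data$is_old & !.data$recognized),
      recollected = sum(.data$recollected_correct %in% TRUE),
      n_old = sum(.data$is_old),
      n_new = sum(!.data$is_old),
      .groups = "drop"
    )
  if (any(counts$n_old == 0 | counts$n_new == 0)) {
    abort("every subject x valence cell needs both old and new trials",
          class = "lcarousal_validation_error")
  }
  counts
}

# Extreme-proportion correction ahead of the z-transform.
correct_rate <- function(k, n, method = c("ratio", "loglinear")) {
  method <- match.arg(method)
  if (method == "loglinear") return((k + 0.5) / (n + 1))
  r <- k / n
  r[r == 0] <- 1 / (2 * n[r == 0])
  r[r == 1] <- 1 - 1 / (2 * n[r == 1])
  r
}

#' Equal-variance SDT indices with extreme-rate correction
#'
#' Computes, per subject x valence, the ceiling/floor-corrected hit and
#' false-alarm rates, sensitivity `d' = z(H) - z(F)`, criterion
#' `c = -(z(H) + z(F))/2` and the likelihood-ratio response bias
#' `beta = exp(d' * c)`. Rates of exactly 0 or 1 are replaced by `1/(2N)`
#' and `1 - 1/(2N)` (default) or by the log-linear rule.
#'
#' @param counts Output of [tabulate_counts()], or any tibble with `hits`,
#'   `false_alarms`, `n_old`, `n_new` columns.
#' @param correction `"ratio"` (the 1/(2N) rule, default) or `"loglinear"`.
#' @return The input plus `hit_rate`, `fa_rate`, `d_prime`, `criterion_c`,
#'   `beta`.
#' @export
sdt_indices <- function(counts, correction = c("ratio", "loglinear")) {
  correction <- match.arg(correction)
  assert_that(all(c("hits", "false_alarms", "n_old", "n_new") %in% names(counts)),
              "counts must have hits, false_alarms, n_old, n_new")
  assert_that(all(counts$n_old > 0) && all(counts$n_new > 0),
              "n_old and n_new must be positive")
  counts |>
    dplyr::mutate(
      hit_rate = correct_rate(.data$hits, .data$n_old, correction),
      fa_rate = correct_rate(.data$false_alarms, .data$n_new, correction),
      d_prime = qnorm(.data$hit_rate) - qnorm(.data$fa_rate),
      criterion_c = -(qnorm(.data$hit_rate) + qnorm(.data$fa_rate)) / 2,
      beta = exp(.data$d_prime * .data$criterion_c)
    )
}

#' Regress response bias out of recollection rates
#'
#' Fits, separately per group (valence), an across-subject ordinary
#' least-squares regression of the recollection rate on the response bias
#' and returns the residuals re-centered at the group mean, so corrected
#' rates stay on the percentage scale. With zero bias variance the slope is
#' undefined; the raw rates are returned with a warning (residuals of the
#' intercept-only fit plus the mean).
#'
#' @param data Tibble with one row per subject (per group).
#' @param rate,bias,group Column names (strings) of the recollection rate,
#'   the bias measure, and the grouping factor (`NULL` for a single fit).
#' @return `data` plus a `corrected` column.
#' @export
bias_residualize <- function(data, rate = "rate", bias = "beta", group = "valence") {
  groups <- if (is.null(group)) list(data) else split(data, data[[group]])
  out <- purrr::map_dfr(groups, function(d) {
    assert_that(sum(complete.cases(d[, c(rate, bias)])) >= 3,
                "bias residualization needs >= 3 subjects with both values")
    x <- d[[bias]]; y <- d[[rate]]
    if (isTRUE(sd(x, na.rm = TRUE) == 0)) {
      warn("bias has zero variance; returning rates unchanged (mean-re-centered residuals of the intercept-only fit)")
      d$corrected <- y
      return(d)
    }
    fit <- lm(y ~ x, na.action = stats::na.exclude)
    d$corrected <- as.numeric(resid(fit)) + mean(y, na.rm = TRUE)
    d
  })
  out
}

#' Adjusted emotional memory score
#'
#' `E / (E + N)` on the bias-corrected emotional and neutral recollection
#' rates: 0.5 means no emotional advantage, values above 0.5 an emotional
#' memory benefit. Undefined (NA) when `E + N <= 0`.
#'
#' @param corrected_emotional,corrected_neutral Bias-corrected rates.
#' @return Numeric score(s) in `[0, 1]`, NA where undefined.
#' @export
adjusted_emotional_score <- function(corrected_emotional, corrected_neutral) {
  tot <- corrected_emotional + corrected_neutral
  out <- ifelse(is.na(tot) | tot <= 0, NA_real_, corrected_emotional / tot)
  if (any(!is.na(tot) & tot <= 0)) {
    warn("adjusted emotional score undefined where E + N <= 0; flagged as NA")
  }
  out
}

# Wilcoxon signed-rank Z with tie and continuity corrections. Returns the
# signed normal deviate (positive when a tends to exceed b) and two-sided p.
signed_rank_z <- function(a, b) {
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p = 1, n = 0))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(list(statistic = 0, p = 1, n = n))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
  list(statistic = z, p = 2 * pnorm(-abs(z)), n = n)
}

#' Paired comparison of two measurement vectors
#'
#' Wilcoxon signed-rank test (normal approximation with tie and continuity
#' corrections, reporting the signed Z statistic) or a paired t-test.
#'
#' @param values_a,values_b Paired numeric vectors.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return Tibble: `method`, `statistic` (Z or t), `p_value`, `n`.
#' @export
paired_compare <- function(values_a, values_b, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  assert_that(length(values_a) == length(values_b), "inputs must be paired")
  keep <- complete.cases(values_a, values_b)
  a <- values_a[keep]; b <- values_b[keep]
  if (method == "wilcoxon") {
    assert_that(length(a) >= 5, "wilcoxon needs >= 5 pairs")
    res <- signed_rank_z(a, b)
    return(tibble::tibble(method = "wilcoxon", statistic = res$statistic,
                          p_value = res$p, n = length(a)))
  }
  if (all(a == b)) {
    return(tibble::tibble(method = "t", statistic = 0, p_value = 1, n = length(a)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(method = "t", statistic = unname(tt$statistic),
                 p_value = tt$p.value, n = length(a))
}

#' Per-subject behavioral scores for the full memory task
#'
#' Runs the complete behavioral chain: recognition counts, SDT indices with
#' extreme-rate correction, raw and recognition-conditional recollection
#' rates, across-subject bias residualization (per valence), and the
#' adjusted emotional memory score.
#'
#' @param trials Trial table (see [tabulate_counts()]).
#' @param correction Extreme-rate correction passed to [sdt_indices()].
#' @return Tibble with one row per subject x valence (rates, d', c, beta,
#'   corrected recollection rate) plus per-subject `adjusted_score`.
#' @export
behavior_scores <- function(trials, correction = "ratio") {
  idx <- sdt_indices(tabulate_counts(trials), correction)
  idx <- idx |>
    dplyr::mutate(
      recollection_raw = 100 * .data$recollected / .data$n_old,
      recollection_conditional = ifelse(.data$hits > 0,
                                        100 * .data$recollected / .data$hits,
                                        NA_real_),
      hit_rate_pct = 100 * .data$hits / .data$n_old,
      fa_rate_pct = 100 * .data$false_alarms / .data$n_new
    )
  corrected <- bias_residualize(idx, rate = "recollection_conditional",
                                bias = "beta", group = "valence")
  wide <- corrected |>
    dplyr::select("subject", "valence", "corrected") |>
    tidyr::pivot_wider(names_from = "valence", values_from = "corrected")
  wide$adjusted_score <- adjusted_emotional_score(wide$emotional, wide$neutral)
  dplyr::left_join(corrected,
                   dplyr::select(wide, "subject", "adjusted_score"),
                   by = "subject")
}

#' Summary table of behavioral scores (median, IQR, paired Wilcoxon)
#'
#' Produces the per-measure emotional-vs-neutral group summary: medians,
#' interquartile ranges, and the paired signed-rank Z and p-value.
#'
#' @param scores Output of [behavior_scores()].
#' @return Tibble: one row per measure.
#' @export
behavior_summary <- function(scores) {
  measures <- c(
    hit_rate_pct = "Recognition hit rate (%)",
    fa_rate_pct = "Recognition false alarm rate (%)",
    beta = "Recognition response bias (beta)",
    recollection_raw = "Recollection hit rate, raw (%)",
    recollection_conditional = "Recollection hit rate | recognition (%)",
    corrected = "Bias-corrected recollection hit rate (%)"
  )
  purrr::map_dfr(names(measures), function(m) {
    wide <- scores |>
      dplyr::select("subject", "valence", dplyr::all_of(m)) |>
      tidyr::pivot_wider(names_from = "valence", values_from = dplyr::all_of(m))
    test <- paired_compare(wide$emotional, wide$neutral, "wilcoxon")
    qs_e <- quantile(wide$emotional, c(0.25, 0.5, 0.75), na.rm = TRUE)
    qs_n <- quantile(wide$neutral, c(0.25, 0.5, 0.75), na.rm = TRUE)
    tibble::tibble(
      measure = measures[[m]],
      emotional_median = qs_e[[2]], emotional_q1 = qs_e[[1]], emotional_q3 = qs_e[[3]],
      neutral_median = qs_n[[2]], neutral_q1 = qs_n[[1]], neutral_q3 = qs_n[[3]],
      z = test$statistic, p_value = test$p_value, n = test$n
    )
  })
}
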