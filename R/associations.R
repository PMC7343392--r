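# Association module: repeated-measures correlation with bootstrap CIs,
# Pearson correlation, random-intercept mixed models, Tukey-adjusted
# marginal contrasts, Johnson-Neyman regions of significance, FDR.

#' Repeated-measures correlation
#'
#' The common within-subject association between two repeatedly measured
#' variables, estimated by analysis of covariance: `y ~ subject + x` with
#' subject as a factor removes between-subject differences; the correlation
#' is `sign(slope) * sqrt(SS_x / (SS_x + SS_error))` with
#' `df = n_obs - n_subjects - 1`, and the p-value comes from the F test of
#' the common slope.
#'
#' Subjects with fewer than two complete pairs cannot contribute a
#' within-subject slope and are dropped with a warning.
#'
#' @param data Long-format data frame.
#' @param x,y Column names (strings) of the two measures.
#' @param subject Subject identifier column.
#' @return Object of class `lc_rmcorr`: `r`, `df`, `p_value`,
#'   `n_subjects`, `n_obs`, `ci` (NULL until [rmcorr_bootstrap()]).
#' @export
rmcorr <- function(data, x, y, subject = "subject") {
  d <- data[complete.cases(data[, c(subject, x, y)]), c(subject, x, y)]
  names(d) <- c("subject", "x", "y")
  counts <- table(d$subject)
  drop <- names(counts)[counts < 2]
  if (length(drop) > 0) {
    warn(sprintf("dropping %d subject(s) with fewer than 2 complete pairs",
                 length(drop)))
    d <- d[!d$subject %in% drop, ]
  }
  n_subj <- length(unique(d$subject))
  assert_that(n_subj >= 2, "repeated-measures correlation needs >= 2 usable subjects")
  d$subject <- factor(d$subject)
  fit <- lm(y ~ subject + x, data = d)
  an <- anova(fit)
  ss_x <- an["x", "Sum Sq"]; ss_err <- an["Residuals", "Sum Sq"]
  r <- sign(coef(fit)[["x"]]) * sqrt(ss_x / (ss_x + ss_err))
  structure(
    list(r = unname(r), df = an["Residuals", "Df"],
         p_value = an["x", "Pr(>F)"],
         n_subjects = n_subj, n_obs = nrow(d), ci = NULL, n_boot = NULL,
         data = tibble::as_tibble(d)),
    class = "lc_rmcorr"
  )
}

#' @export
print.lc_rmcorr <- function(x, ...) {
  cat(sprintf("Repeated-measures correlation: r_rm(%d) = %.3f, p = %.4g (%d subjects, %d observations)\n",
              x$df, x$r, x$p_value, x$n_subjects, x$n_obs))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap 95%% CI [%.3f, %.3f] (%d resamples)\n",
                x$ci[1], x$ci[2], x$n_boot))
  }
  invisible(x)
}

#' Bootstrap confidence interval for the repeated-measures correlation
#'
#' Subjects are resampled with replacement (each draw keeps all of a
#' subject's observations under a fresh id); degenerate resamples that
#' leave fewer than two usable subjects or no within-subject variance are
#' redrawn. Percentile CI.
#'
#' @param fit An [rmcorr()] result (or a data frame plus `x`, `y`,
#'   `subject` as in [rmcorr()]).
#' @param n_boot Number of bootstrap resamples (5000).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @param ... Passed to [rmcorr()] when `fit` is a data frame.
#' @return The `lc_rmcorr` object with `ci` and `n_boot` filled in.
#' @export
rmcorr_bootstrap <- function(fit, n_boot = 5000, seed = 1, conf = 0.95, ...) {
  if (!inherits(fit, "lc_rmcorr")) fit <- rmcorr(fit, ...)
  d <- fit$data
  subjects <- unique(d$subject)
  by_subj <- split(d, d$subject)
  boot_r <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      repeat {
        draw <- sample(subjects, length(subjects), replace = TRUE)
        picked <- by_subj[as.character(draw)]
        rs <- dplyr::bind_rows(picked)
        rs$subject <- rep(seq_along(draw), times = vapply(picked, nrow, 1L))
        if (length(unique(rs$subject)) < 2) next
        r <- tryCatch({
          f <- lm(y ~ factor(subject) + x, data = rs)
          an <- anova(f)
          ss_x <- an["x", "Sum Sq"]; ss_e <- an["Residuals", "Sum Sq"]
          if (!is.finite(ss_x) || ss_x + ss_e == 0) NA_real_
          else sign(coef(f)[["x"]]) * sqrt(ss_x / (ss_x + ss_e))
        }, error = function(e) NA_real_)
        if (!is.na(r)) return(r)
      }
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  fit$ci <- unname(quantile(boot_r, c(alpha, 1 - alpha)))
  fit$n_boot <- n_boot
  fit
}

#' Pearson product-moment correlation with t-based p-value
#'
#' @param data Data frame (or NULL to use `x`, `y` as numeric vectors).
#' @param x,y Column names, or numeric vectors when `data` is NULL.
#' @return Tibble: `r`, `statistic` (t), `df`, `p_value`, `n`.
#' @export
pearson_assoc <- function(data = NULL, x, y) {
  if (!is.null(data)) { xv <- data[[x]]; yv <- data[[y]] } else { xv <- x; yv <- y }
  keep <- complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  assert_that(length(xv) >= 3, "Pearson correlation needs >= 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("zero variance in one of the variables",
          class = "lcarousal_validation_error")
  }
  ct <- cor.test(xv, yv, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value, n = length(xv))
}

#' Random-intercept linear mixed model over task stages
#'
#' Fits `outcome ~ predictor * stage + (1 | subject)` (or the reduced forms
#' without predictor or interaction) by maximum likelihood, with
#' Satterthwaite degrees of freedom for the coefficient t tests. Stage uses
#' treatment coding with the first level (baseline, if present) as
#' reference. A singular random-effect fit triggers a warning and an
#' ordinary least-squares refit without the random intercept.
#'
#' @param data Long-format data frame with a subject column.
#' @param outcome Outcome column name.
#' @param predictor Optional continuous/factor predictor column.
#' @param stage Stage (factor) column; `NULL` for predictor-only models.
#' @param interaction Include the predictor x stage interaction.
#' @param subject Subject id column.
#' @return Object of class `lc_lmm`: `fit` (lmerModLmerTest or lm),
#'   `coefficients` tibble (estimate, SE, df, t, p), `formula`, `singular`.
#' @export
stage_lmm <- function(data, outcome, predictor = NULL, stage = "stage",
                      interaction = !is.null(predictor) && !is.null(stage),
                      subject = "subject") {
  assert_that(subject %in% names(data), "subject column missing")
  d <- as.data.frame(data)
  if (!is.null(stage)) {
    lv <- unique(as.character(d[[stage]]))
    if ("baseline" %in% lv) lv <- c("baseline", setdiff(lv, "baseline"))
    d[[stage]] <- factor(d[[stage]], levels = lv)
  }
  rhs <- c()
  if (!is.null(predictor)) rhs <- c(rhs, predictor)
  if (!is.null(stage)) rhs <- c(rhs, stage)
  if (interaction) rhs <- c(rhs, paste0(predictor, ":", stage))
  fml <- as.formula(paste(outcome, "~", paste(rhs, collapse = " + "),
                          "+ (1 |", subject, ")"))
  fit <- suppressMessages(
    lmerTest::lmer(fml, data = d, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warn("singular random-intercept fit; refitting without the random intercept")
    fml_red <- as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
    fit <- lm(fml_red, data = d)
    cf <- summary(fit)$coefficients
    coefs <- tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                            std_error = cf[, 2],
                            df = stats::df.residual(fit),
                            statistic = cf[, 3], p_value = cf[, 4])
  } else {
    cf <- summary(fit)$coefficients # Satterthwaite df via lmerTest
    coefs <- tibble::tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                            std_error = cf[, "Std. Error"], df = cf[, "df"],
                            statistic = cf[, "t value"],
                            p_value = cf[, "Pr(>|t|)"])
  }
  structure(list(fit = fit, coefficients = coefs, formula = fml,
                 singular = singular, data = tibble::as_tibble(d),
                 outcome = outcome, predictor = predictor, stage = stage,
                 subject = subject),
            class = "lc_lmm")
}

#' @export
print.lc_lmm <- function(x, ...) {
  cat("Random-intercept mixed model:", deparse(x$formula), "\n")
  if (x$singular) cat("  (singular random intercept; OLS refit)\n")
  print(x$coefficients)
  invisible(x)
}

#' Pairwise marginal-mean contrasts with Tukey adjustment
#'
#' Estimated marginal means for the factor's levels and all pairwise
#' differences, p-values adjusted with the studentized-range (Tukey)
#' method.
#'
#' @param model An [stage_lmm()] result (or an lmer/lm fit).
#' @param factor_name Factor whose levels are compared.
#' @param adjust Adjustment method (`"tukey"`).
#' @return Tibble: `contrast`, `estimate`, `std_error`, `df`, `statistic`,
#'   `p_value`.
#' @export
marginal_contrasts <- function(model, factor_name = "stage", adjust = "tukey") {
  fit <- if (inherits(model, "lc_lmm")) model$fit else model
  vars <- all.vars(stats::formula(fit))
  if (!factor_name %in% vars) {
    abort(paste("factor not in model:", factor_name),
          class = "lcarousal_validation_error")
  }
  emm <- emmeans::emmeans(fit, specs = factor_name,
                          lmer.df = "satterthwaite")
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = adjust))
  tibble::tibble(contrast = as.character(prs$contrast), estimate = prs$estimate,
                 std_error = prs$SE, df = prs$df, statistic = prs$t.ratio,
                 p_value = prs$p.value)
}

# Conditional stage-pair difference delta(f) = a0 + a1 * f and its variance
# from the fixed-effect vector and covariance of a stage x moderator model.
stage_pair_contrast <- function(fit, stage_var, moderator, level_a, level_b) {
  beta <- if (inherits(fit, "lmerMod")) lme4::fixef(fit) else coef(fit)
  V <- as.matrix(vcov(fit))
  nm <- names(beta)
  main_term <- function(level) {
    t1 <- paste0(stage_var, level)
    if (t1 %in% nm) t1 else NA_character_
  }
  int_term <- function(level) {
    cands <- c(paste0(stage_var, level, ":", moderator),
               paste0(moderator, ":", stage_var, level))
    hit <- cands[cands %in% nm]
    if (length(hit) > 0) hit[1] else NA_character_
  }
  cvec0 <- setNames(numeric(length(nm)), nm) # coefficient weights for a0
  cvec1 <- setNames(numeric(length(nm)), nm) # weights for a1 (slope in f)
  for (s in list(list(level_a, 1), list(level_b, -1))) {
    mt <- main_term(s[[1]]); it <- int_term(s[[1]])
    if (!is.na(mt)) cvec0[mt] <- cvec0[mt] + s[[2]]
    if (!is.na(it)) cvec1[it] <- cvec1[it] + s[[2]]
  }
  a0 <- sum(cvec0 * beta); a1 <- sum(cvec1 * beta)
  v00 <- drop(t(cvec0) %*% V %*% cvec0)
  v11 <- drop(t(cvec1) %*% V %*% cvec1)
  v01 <- drop(t(cvec0) %*% V %*% cvec1)
  list(a0 = a0, a1 = a1, v00 = v00, v01 = v01, v11 = v11)
}

#' Johnson-Neyman region of significance for a stage x moderator interaction
#'
#' For each stage pair in a model `outcome ~ stage * moderator + (1|subject)`
#' the conditional difference `delta(f) = a0 + a1 f` is significant where
#' `delta(f)^2 > t_crit^2 Var(delta(f))`; the boundaries are the real roots
#' of the implied quadratic, intersected with the observed moderator range.
#' With no sign change the region is declared empty or full.
#'
#' @param model An [stage_lmm()] fit with a stage-by-moderator interaction.
#' @param moderator Moderator column name (e.g. frequency in Hz).
#' @param alpha Significance level (0.05).
#' @return Tibble per stage pair: `stage_a`, `stage_b`, `lower`, `upper`,
#'   `region` ("inside", "outside", "all", "none").
#' @export
region_of_significance <- function(model, moderator = "frequency",
                                   alpha = 0.05) {
  stopifnot(inherits(model, "lc_lmm"))
  fit <- model$fit
  stage_var <- model$stage
  levels_ <- levels(model$data[[stage_var]])
  rng <- range(model$data[[moderator]], na.rm = TRUE)
  dfree <- if (inherits(fit, "lmerMod")) {
    nrow(model$data) - length(lme4::fixef(fit))
  } else stats::df.residual(fit)
  tcrit <- qt(1 - alpha / 2, dfree)
  pairs_ <- utils::combn(levels_, 2, simplify = FALSE)
  purrr::map_dfr(pairs_, function(pr) {
    ct <- stage_pair_contrast(fit, stage_var, moderator, pr[2], pr[1])
    # delta(f)^2 = t^2 var(f): quadratic A f^2 + B f + C = 0
    A <- ct$a1^2 - tcrit^2 * ct$v11
    B <- 2 * (ct$a0 * ct$a1 - tcrit^2 * ct$v01)
    C <- ct$a0^2 - tcrit^2 * ct$v00
    sig_at <- function(f) {
      (ct$a0 + ct$a1 * f)^2 > tcrit^2 * (ct$v00 + 2 * f * ct$v01 + f^2 * ct$v11)
    }
    disc <- B^2 - 4 * A * C
    roots <- if (abs(A) < 1e-300) {
      if (abs(B) < 1e-300) numeric(0) else -C / B
    } else if (disc < 0) numeric(0) else {
      sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
    }
    roots <- roots[roots > rng[1] & roots < rng[2]]
    region <- if (length(roots) == 0) {
      if (sig_at(mean(rng))) "all" else "none"
    } else if (length(roots) == 1) {
      if (sig_at(rng[1])) "below" else "above"
    } else {
      if (sig_at(mean(roots))) "inside" else "outside"
    }
    tibble::tibble(
      stage_a = pr[2], stage_b = pr[1],
      lower = if (length(roots) >= 1) roots[1] else NA_real_,
      upper = if (length(roots) >= 2) roots[2] else
        if (length(roots) == 1) roots[1] else NA_real_,
      region = region
    )
  })
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `min over k >= i of m p_(k) / k`, monotone,
#' capped at 1.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
fdr_adjust <- function(p) {
  assert_that(is_prob(p[!is.na(p)]), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
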