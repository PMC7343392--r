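# Repeated-measures correlation, Pearson, mixed models, Tukey contrasts,
# Johnson-Neyman regions, FDR.

test_that("rmcorr is exact on deterministic within-subject structure", {
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:6), x = c(1, 2, 3, 4))
  offs <- setNames(seq(0, 50, by = 10), unique(d$subject))
  d$y <- d$x + offs[d$subject]
  expect_equal(rmcorr(d, "x", "y")$r, 1)
  d$y2 <- -d$x + offs[d$subject]
  expect_equal(rmcorr(d, "x", "y2")$r, -1)
  expect_equal(rmcorr(d, "x", "y")$df, nrow(d) - 6 - 1)
})

test_that("rmcorr agrees with the subject-demeaning oracle and recovers truth", {
  withr::with_seed(8, {
    d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:12), rep = 1:4)
    d$x <- rnorm(nrow(d))
    d$y <- 0.6 * d$x + rep(rnorm(12, 0, 2), each = 4) + rnorm(nrow(d), 0, 0.8)
  })
  fit <- rmcorr(d, "x", "y")
  # independent route: correlation of subject-demeaned residuals
  rx <- resid(lm(x ~ factor(subject), data = d))
  ry <- resid(lm(y ~ factor(subject), data = d))
  expect_equal(fit$r, cor(rx, ry), tolerance = 1e-12)

  # parameter recovery: common within-subject correlation 0.5
  withr::with_seed(15, {
    r_hat <- vapply(1:200, function(i) {
      dd <- tidyr::expand_grid(subject = 1:20, stage = 1:4)
      dd$x <- rnorm(nrow(dd))
      dd$y <- dd$x + sqrt(1 - 0.5^2) / 0.5 * rnorm(nrow(dd)) +
        rep(rnorm(20, 0, 3), each = 4)
      rmcorr(dd, "x", "y")$r
    }, numeric(1))
  })
  expect_equal(mean(r_hat), 0.5, tolerance = 0.05 / 0.5)

  # subjects with a single observation are dropped with a warning
  d1 <- dplyr::bind_rows(d, tibble::tibble(subject = "s99", rep = 1,
                                           x = 1, y = 1))
  expect_warning(fit1 <- rmcorr(d1, "x", "y"), "fewer than 2")
  expect_equal(fit1$n_subjects, 12)
  expect_error(suppressWarnings(
    rmcorr(tibble::tibble(subject = c("a", "b"), x = 1:2, y = 2:3),
           "x", "y")),
    class = "lcarousal_config_error")
})

test_that("the subject bootstrap yields sane percentile intervals", {
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:8), x = c(1, 2, 3))
  offs <- setNames(seq(0, 70, by = 10), unique(d$subject))
  d$y <- 2 * d$x + offs[d$subject]
  fit <- rmcorr_bootstrap(rmcorr(d, "x", "y"), n_boot = 200, seed = 4)
  expect_equal(unname(fit$ci), c(1, 1))

  # CI contains the point estimate across simulated datasets
  withr::with_seed(22, {
    contains <- vapply(1:25, function(i) {
      dd <- tidyr::expand_grid(subject = 1:10, rep = 1:4)
      dd$x <- rnorm(40)
      dd$y <- 0.5 * dd$x + rep(rnorm(10), each = 4) + rnorm(40, 0, 0.7)
      f <- rmcorr_bootstrap(rmcorr(dd, "x", "y"), n_boot = 300, seed = i)
      f$ci[1] <= f$r && f$r <= f$ci[2]
    }, logical(1))
  })
  expect_gte(mean(contains), 0.96)

  # reproducible under a fixed seed
  f1 <- rmcorr_bootstrap(rmcorr(d, "x", "y"), n_boot = 100, seed = 9)
  f2 <- rmcorr_bootstrap(rmcorr(d, "x", "y"), n_boot = 100, seed = 9)
  expect_identical(f1$ci, f2$ci)
})

test_that("tidiers expose rmcorr results in broom shape", {
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:6), x = c(1, 2, 3, 4))
  d$y <- d$x + rep(1:6, each = 4) + c(0.01 * sin(seq_len(nrow(d))))
  fit <- rmcorr_bootstrap(rmcorr(d, "x", "y"), n_boot = 100, seed = 1)
  td <- generics::tidy(fit)
  expect_named(td, c("estimate", "df", "p.value", "conf.low", "conf.high"))
  gl <- generics::glance(fit)
  expect_equal(gl$n_subjects, 6)
})

test_that("Pearson association matches closed-form values", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  expect_equal(pearson_assoc(d, "x", "y")$r, 1)

  # exact r = 0.452 at n = 18: the t transform gives p ~ 0.0597
  pr <- exact_cor_pair(18, 0.452)
  res <- pearson_assoc(x = pr$x, y = pr$y)
  expect_equal(res$r, 0.452, tolerance = 1e-10)
  expect_equal(res$p_value, 0.059677, tolerance = 1e-4)

  # designed orthogonality: r = 0
  d0 <- tibble::tibble(x = c(-1, 0, 1, -1, 0, 1), y = c(1, -2, 1, 1, -2, 1))
  expect_equal(pearson_assoc(d0, "x", "y")$r, 0)

  expect_error(pearson_assoc(tibble::tibble(x = rep(1, 5), y = 1:5), "x", "y"),
               class = "lcarousal_validation_error")
  expect_error(pearson_assoc(x = 1:2, y = 1:2), "3 complete pairs")
})

test_that("stage mixed models recover known coefficients", {
  # zero-noise data: coefficients reproduced exactly (OLS refit after the
  # degenerate random-intercept fit)
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:8),
                          stage = c("baseline", "encoding",
                                    "consolidation", "recollection"))
  truth <- c(baseline = 0, encoding = 10, consolidation = 60, recollection = 10)
  d$y <- 5 + truth[d$stage]
  fit <- suppressWarnings(stage_lmm(d, "y"))
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "(Intercept)"] - 5), 1e-6)
  expect_lt(abs(co$estimate[co$term == "stageconsolidation"] - 60), 1e-6)

  # with real between-subject variance the random intercept is retained and
  # the stage effect is recovered within 2 SE
  withr::with_seed(33, {
    d$y <- 5 + truth[d$stage] + rep(rnorm(8, 0, 6), each = 4) + rnorm(32, 0, 3)
  })
  fit2 <- stage_lmm(d, "y")
  expect_false(fit2$singular)
  co2 <- fit2$coefficients[fit2$coefficients$term == "stageconsolidation", ]
  expect_lt(abs(co2$estimate - 60), 2 * co2$std_error)
  expect_true(all(is.finite(co2$df)))
  # baseline is the reference level
  expect_false("stagebaseline" %in% fit2$coefficients$term)
})

test_that("Tukey-adjusted marginal contrasts behave canonically", {
  withr::with_seed(44, {
    d <- tidyr::expand_grid(subject = sprintf("s%d", 1:10),
                            stage = c("baseline", "encoding",
                                      "consolidation", "recollection"))
    d$y <- rep(rnorm(10, 0, 2), each = 4) + rnorm(40) +
      ifelse(d$stage == "consolidation", 4, 0)
  })
  fit <- stage_lmm(d, "y")
  ctr <- marginal_contrasts(fit, "stage")
  expect_equal(nrow(ctr), 6)
  # contrast estimates sum to zero over a closed cycle
  g <- function(a, b) {
    i <- which(ctr$contrast == paste(a, "-", b))
    if (length(i)) ctr$estimate[i] else -ctr$estimate[ctr$contrast == paste(b, "-", a)]
  }
  expect_equal(g("baseline", "encoding") + g("encoding", "consolidation") +
                 g("consolidation", "baseline"), 0, tolerance = 1e-10)

  # two-level factor: Tukey p equals the unadjusted p
  d2 <- d[d$stage %in% c("baseline", "consolidation"), ]
  fit2 <- stage_lmm(d2, "y")
  tk <- marginal_contrasts(fit2, "stage")
  un <- marginal_contrasts(fit2, "stage", adjust = "none")
  expect_equal(tk$p_value, un$p_value, tolerance = 1e-12)

  expect_error(marginal_contrasts(fit, "colour"),
               class = "lcarousal_validation_error")
})

test_that("Johnson-Neyman boundaries match a dense grid-scan oracle", {
  # crossover: the stage effect on coherence reverses sign at f0 = 0.25 Hz
  withr::with_seed(55, {
    d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:16),
                            stage = c("baseline", "encoding"),
                            frequency = seq(0.01, 0.5, length.out = 45))
    d$msc <- 0.4 + ifelse(d$stage == "encoding", 0.8 * (d$frequency - 0.25), 0) +
      rep(rnorm(16, 0, 0.05), each = 90) + rnorm(nrow(d), 0, 0.08)
  })
  fit <- stage_lmm(d, "msc", predictor = "frequency", interaction = TRUE)
  ros <- region_of_significance(fit, moderator = "frequency")
  expect_equal(nrow(ros), 1)
  expect_equal(ros$region, "outside") # significant below lower and above upper

  # brute-force oracle: pointwise t tests on a dense moderator grid with the
  # same df convention; boundaries are where significance flips
  grid <- seq(0.01, 0.5, length.out = 2000)
  beta <- lme4::fixef(fit$fit); V <- as.matrix(vcov(fit$fit))
  nm <- names(beta)
  it <- grep(":", nm, value = TRUE)
  st <- setdiff(grep("stage", nm, value = TRUE), it)
  dfree <- nrow(fit$data) - length(beta)
  tcrit <- qt(0.975, dfree)
  sig <- vapply(grid, function(f) {
    cv <- setNames(numeric(length(nm)), nm)
    cv[st] <- 1; cv[it] <- f
    est <- sum(cv * beta); se <- sqrt(drop(t(cv) %*% V %*% cv))
    abs(est / se) > tcrit
  }, logical(1))
  flips <- grid[which(diff(sig) != 0)]
  expect_equal(length(flips), 2)
  step <- diff(grid)[1]
  expect_lt(abs(ros$lower - flips[1]), 0.02)
  expect_lt(abs(ros$upper - flips[2]), 0.02)

  # boundaries are equivariant under moderator rescaling (Hz -> mHz)
  d_mhz <- dplyr::mutate(d, frequency = frequency * 1000)
  fit_mhz <- stage_lmm(d_mhz, "msc", predictor = "frequency",
                       interaction = TRUE)
  ros_mhz <- region_of_significance(fit_mhz, moderator = "frequency")
  expect_equal(ros_mhz$lower / 1000, ros$lower, tolerance = 1e-6)
  expect_equal(ros_mhz$upper / 1000, ros$upper, tolerance = 1e-6)

  # no interaction in truth: the region is empty or full
  withr::with_seed(66, {
    d0 <- d; d0$msc <- 0.4 + rep(rnorm(16, 0, 0.05), each = 90) +
      rnorm(nrow(d0), 0, 0.08)
  })
  fit0 <- stage_lmm(d0, "msc", predictor = "frequency", interaction = TRUE)
  ros0 <- region_of_significance(fit0, moderator = "frequency")
  expect_true(ros0$region %in% c("none", "all"))
})

test_that("Benjamini-Hochberg adjustment matches the hand-traced example", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(1), 1)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(77, p <- runif(30)^2)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "lcarousal_config_error")
})
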