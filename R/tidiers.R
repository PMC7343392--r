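# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a repeated-measures correlation
#'
#' @param x An `lc_rmcorr`.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `df`, `p.value`, `conf.low`,
#'   `conf.high`.
#' @method tidy lc_rmcorr
#' @export
tidy.lc_rmcorr <- function(x, ...) {
  tibble::tibble(
    estimate = x$r, df = x$df, p.value = x$p_value,
    conf.low = if (is.null(x$ci)) NA_real_ else x$ci[1],
    conf.high = if (is.null(x$ci)) NA_real_ else x$ci[2]
  )
}

#' @rdname tidy.lc_rmcorr
#' @method glance lc_rmcorr
#' @export
glance.lc_rmcorr <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_obs = x$n_obs,
                 n_boot = x$n_boot %||% NA_integer_)
}

#' Tidy a stage mixed model
#'
#' @param x An `lc_lmm`.
#' @param ... Unused.
#' @return Coefficient tibble: `term`, `estimate`, `std.error`, `df`,
#'   `statistic`, `p.value`.
#' @method tidy lc_lmm
#' @export
tidy.lc_lmm <- function(x, ...) {
  dplyr::rename(x$coefficients, std.error = "std_error", p.value = "p_value")
}

#' @rdname tidy.lc_lmm
#' @method glance lc_lmm
#' @export
glance.lc_lmm <- function(x, ...) {
  ll <- stats::logLik(x$fit)
  tibble::tibble(logLik = as.numeric(ll), df = attr(ll, "df"),
                 AIC = stats::AIC(x$fit), BIC = stats::BIC(x$fit),
                 singular = x$singular, nobs = nrow(x$data))
}

#' Tidy a band of maximum coherence
#'
#' @param x A `max_coh_band`.
#' @param ... Unused.
#' @return One-row tibble: `median`, `conf.low`, `conf.high`, `n_subjects`.
#' @method tidy max_coh_band
#' @export
tidy.max_coh_band <- function(x, ...) {
  tibble::tibble(median = x$median, conf.low = x$lower, conf.high = x$upper,
                 n_subjects = nrow(x$peaks))
}
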