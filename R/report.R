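# Human-readable report generation from a pipeline result bundle.

fmt_num <- function(x, digits = 3) formatC(x, format = "f", digits = digits)

md_table <- function(df, digits = 3) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                        ~ fmt_num(.x, digits)))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, rows)
}

#' Render a pipeline result bundle as a Markdown report
#'
#' Produces a plain-Markdown summary of the behavioral table, stage
#' measures, the coherence band, surrogate tests and association
#' statistics. Every number is taken verbatim from the result bundle (no
#' recomputation), so regeneration is idempotent.
#'
#' @param results An `lc_report` from [run_all()].
#' @return Character vector of Markdown lines.
#' @export
make_report <- function(results) {
  stopifnot(inherits(results, "lc_report"))
  lines <- c(
    "# Arousal-memory pipeline report", "",
    sprintf("Seed: %d; config hash: `%s`; bootstrap resamples: %d; surrogates per subject: %d",
            results$provenance$seed, results$provenance$config_hash,
            results$provenance$n_boot, results$provenance$n_surrogates),
    "", "## Behavioral summary (emotional vs neutral)", "",
    md_table(results$behavior_summary, 2), "",
    "## Stage measures (group medians)", ""
  )
  med <- results$stage_measures |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      rmssd = median(.data$rmssd, na.rm = TRUE),
      delta_saa = median(.data$delta_saa, na.rm = TRUE),
      lc_variance = median(.data$lc_variance, na.rm = TRUE),
      band_msc = median(.data$band_msc, na.rm = TRUE),
      n_usable = sum(.data$usable), .groups = "drop")
  lines <- c(lines, md_table(med, 3), "",
             "## Band of maximum LC-HRV coherence", "",
             sprintf("Median argmax frequency %s Hz, 95%% CI [%s, %s] Hz (%d subjects).",
                     fmt_num(results$band$median), fmt_num(results$band$lower),
                     fmt_num(results$band$upper), nrow(results$band$peaks)), "")
  if (!is.null(results$coherence_tests) && nrow(results$coherence_tests) > 0) {
    lines <- c(lines, "## LC-HRV coherence vs AR(1)-surrogate null", "",
               md_table(results$coherence_tests, 4), "")
  }
  if (!is.null(results$partial_tests) && nrow(results$partial_tests) > 0) {
    lines <- c(lines, "## Partial coherence (LC-amygdala | hippocampus) vs surrogate null", "",
               md_table(results$partial_tests, 4), "")
  }
  lines <- c(lines, "## Associations", "",
             md_table(results$associations, 4), "")
  if (!is.null(results$region_of_significance) &&
      nrow(results$region_of_significance) > 0) {
    lines <- c(lines, "## Johnson-Neyman regions (coherence ~ stage x frequency)", "",
               md_table(results$region_of_significance, 3), "")
  }
  lines
}

#' Write a result bundle to disk (TSV tables + JSON summary + Markdown)
#'
#' @param results An `lc_report`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  stopifnot(inherits(results, "lc_report"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(results$behavior, file.path(path, "behavior_scores.tsv"))
  readr::write_tsv(results$behavior_summary, file.path(path, "behavior_summary.tsv"))
  readr::write_tsv(results$stage_measures, file.path(path, "stage_measures.tsv"))
  readr::write_tsv(results$profiles, file.path(path, "coherence_profiles.tsv"))
  readr::write_tsv(results$associations, file.path(path, "associations.tsv"))
  jsonlite::write_json(
    list(band = list(median = results$band$median, lower = results$band$lower,
                     upper = results$band$upper),
         provenance = results$provenance),
    file.path(path, "band.json"), auto_unbox = TRUE, digits = NA)
  writeLines(make_report(results), file.path(path, "report.md"))
  invisible(path)
}
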