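# Pipeline module: dataset I/O, validation, and end-to-end orchestration.

#' Write a study dataset to a directory of TSV files
#'
#' Layout: `trials.tsv`, `beats_<subject>_<stage>.tsv`,
#' `roi_<subject>_<stage>.tsv`, `saa.tsv`, plus `config.yaml` and (for
#' simulated data) `ground_truth.json`.
#'
#' @param study A `study_dataset`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$trials, file.path(path, "trials.tsv"))
  readr::write_tsv(study$saa, file.path(path, "saa.tsv"))
  keys <- dplyr::distinct(study$beats, .data$subject, .data$stage)
  for (k in seq_len(nrow(keys))) {
    subj <- keys$subject[k]; stage <- keys$stage[k]
    b <- dplyr::filter(study$beats, .data$subject == subj, .data$stage == !!stage)
    readr::write_tsv(dplyr::select(b, "time"),
                     file.path(path, sprintf("beats_%s_%s.tsv", subj, stage)))
    r <- dplyr::filter(study$roi, .data$subject == subj, .data$stage == !!stage)
    readr::write_tsv(dplyr::select(r, -"subject", -"stage"),
                     file.path(path, sprintf("roi_%s_%s.tsv", subj, stage)))
  }
  yaml::write_yaml(unclass(study$config), file.path(path, "config.yaml"))
  if (!is.null(study$ground_truth)) {
    strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
    jsonlite::write_json(strip(study$ground_truth),
                         file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Load and validate a study dataset directory
#'
#' Reads the layout written by [write_study()] and validates it: beat
#' timestamps must be strictly increasing, recollection responses must sit
#' on endorsed old trials, and every subject/stage pair named by the config
#' must have beat and ROI files. Violations are reported with file and row.
#'
#' @param path Directory path.
#' @return A `study_dataset`.
#' @export
load_study <- function(path) {
  need <- file.path(path, c("trials.tsv", "saa.tsv", "config.yaml"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    abort(paste("missing mandatory file(s):", paste(basename(missing), collapse = ", ")),
          class = "lcarousal_validation_error")
  }
  cfg_raw <- yaml::read_yaml(file.path(path, "config.yaml"))
  config <- cohort_config(cfg_raw$n_subjects, cfg_raw$stages,
                          cfg_raw$sampling_interval, cfg_raw$series_length,
                          cfg_raw$seed)
  trials <- readr::read_tsv(file.path(path, "trials.tsv"), show_col_types = FALSE)
  bad <- which(!is.na(trials$recollected_correct) &
                 !(trials$is_old & trials$recognized))
  if (length(bad) > 0) {
    abort(sprintf("trials.tsv row %d: recollection response without an endorsed old trial",
                  bad[1]),
          class = "lcarousal_validation_error")
  }
  saa <- readr::read_tsv(file.path(path, "saa.tsv"), show_col_types = FALSE)
  subjects <- unique(trials$subject)
  beats <- list(); roi <- list()
  for (subj in subjects) {
    for (stage in config$stages) {
      bf <- file.path(path, sprintf("beats_%s_%s.tsv", subj, stage))
      rf <- file.path(path, sprintf("roi_%s_%s.tsv", subj, stage))
      for (f in c(bf, rf)) {
        if (!file.exists(f)) {
          abort(paste("missing per-stage file:", basename(f)),
                class = "lcarousal_validation_error")
        }
      }
      b <- readr::read_tsv(bf, show_col_types = FALSE)
      nonmono <- which(diff(b$time) <= 0)
      if (length(nonmono) > 0) {
        abort(sprintf("%s row %d: beat timestamps not strictly increasing",
                      basename(bf), nonmono[1] + 1),
              class = "lcarousal_validation_error")
      }
      beats[[length(beats) + 1]] <-
        dplyr::mutate(b, subject = subj, stage = stage, .before = 1)
      roi[[length(roi) + 1]] <-
        dplyr::mutate(readr::read_tsv(rf, show_col_types = FALSE),
                      subject = subj, stage = stage, .before = 1)
    }
  }
  gt_file <- file.path(path, "ground_truth.json")
  structure(
    list(trials = trials, beats = dplyr::bind_rows(beats),
         roi = dplyr::bind_rows(roi), saa = saa, config = config,
         ground_truth = if (file.exists(gt_file))
           jsonlite::read_json(gt_file, simplifyVector = TRUE) else NULL),
    class = "study_dataset"
  )
}

# Per-subject, per-stage physiological measures: cleaned beats, rMSSD,
# interpolated HRV series, usability.
physio_measures <- function(study, min_bpm = 25, max_bpm = 200,
                            rel_threshold = 0.13, max_missing_pct = 10) {
  cfg <- study$config
  duration <- (cfg$series_length - 1) * cfg$sampling_interval
  keys <- dplyr::distinct(study$beats, .data$subject, .data$stage)
  res <- purrr::map(seq_len(nrow(keys)), function(k) {
    subj <- keys$subject[k]; stage <- keys$stage[k]
    b <- dplyr::filter(study$beats, .data$subject == subj, .data$stage == !!stage)
    cleaned <- tryCatch(
      clean_beats(b$time, min_bpm, max_bpm, rel_threshold),
      lcarousal_unusable_error = function(e) NULL)
    if (is.null(cleaned)) {
      return(list(row = tibble::tibble(subject = subj, stage = stage,
                                       rmssd = NA_real_, percent_missing = 100,
                                       usable = FALSE),
                  series = NULL))
    }
    series <- tryCatch(
      interpolate_hrv(cleaned, cfg$sampling_interval, duration),
      error = function(e) NULL)
    pct <- if (is.null(series)) 100 else attr(series, "percent_missing")
    list(
      row = tibble::tibble(subject = subj, stage = stage,
                           rmssd = rmssd(cleaned), percent_missing = pct,
                           usable = !is.null(series) && hrv_usable(pct, max_missing_pct)),
      series = series
    )
  })
  list(measures = purrr::map_dfr(res, "row"),
       series = setNames(purrr::map(res, "series"),
                         paste(keys$subject, keys$stage, sep = "|")))
}

# Surrogate null of band-median partial coherence for a series triple:
# AR(1)-matched surrogate triples, Welch in one batch, partial coherence
# x-y conditioned on z per surrogate.
partial_coherence_null <- function(x, y, z, band, n_surrogates = 100,
                                   seed = 1, fs = 1, bins = 90,
                                   overlap = 0.2, working_rate = 1) {
  rng <- if (inherits(band, "max_coh_band")) c(band$lower, band$upper) else band
  rate <- working_rate %||% fs
  ser <- lapply(list(x, y, z), function(s) resample_series(s, fs, rate))
  fits <- lapply(ser, fit_ar1)
  n <- length(ser[[1]])
  with_seed(seed, {
    S <- n_surrogates
    mats <- lapply(fits, function(f)
      replicate(S, sim_ar1(n, f$coefficient, sqrt(f$series_variance))))
    wf <- welch_segment_fft(do.call(cbind, mats), rate, bins = bins,
                            overlap = overlap)
    sel <- wf$freq >= rng[1] & wf$freq <= rng[2]
    vapply(seq_len(S), function(s) {
      ids <- c(s, S + s, 2 * S + s)
      P <- array(0i, dim = c(sum(sel), 3, 3))
      fsub <- wf$F[sel, , ids, drop = FALSE]
      for (i in 1:3) {
        for (j in i:3) {
          pij <- rowSums(fsub[, , i, drop = FALSE] * Conj(fsub[, , j, drop = FALSE]))
          dim(pij) <- NULL
          P[, i, j] <- pij
          if (j > i) P[, j, i] <- Conj(pij)
        }
      }
      pc <- vapply(seq_len(dim(P)[1]), function(k) {
        G <- tryCatch(solve(P[k, , ]), error = function(e) NULL)
        if (is.null(G)) return(NA_real_)
        den <- Re(G[1, 1]) * Re(G[2, 2])
        if (den <= 0) NA_real_ else min(max(Mod(G[1, 2])^2 / den, 0), 1)
      }, numeric(1))
      median(pc, na.rm = TRUE)
    }, numeric(1))
  })
}

#' Run the full analysis chain on a study dataset
#'
#' Behavioral scoring, beat cleaning and rMSSD, sAA stage deltas, LC-HRV
#' coherence and phase profiles, the cross-subject band of maximum
#' coherence (from the baseline stage), band-median point estimates,
#' AR(1)-surrogate coherence tests, partial coherence within the ROI
#' network, repeated-measures correlations, stage mixed models with Tukey
#' contrasts, and the coherence-by-frequency interaction model with
#' Johnson-Neyman regions. Deterministic given the config seed.
#'
#' @param study A `study_dataset` or a path for [load_study()].
#' @param n_boot Bootstrap resamples for rmcorr CIs and the band CI.
#' @param n_surrogates Surrogate pairs per subject for the coherence nulls.
#' @param bins,working_rate Spectral grid parameters.
#' @param band_search Frequency range (Hz) searched for each subject's
#'   coherence peak; defaults to the HF-HRV band, additionally capped at
#'   the native Nyquist.
#' @param seed Seed for bootstrap/surrogate randomness; defaults to the
#'   study config seed.
#' @return A list of class `lc_report`.
#' @export
run_all <- function(study, n_boot = 5000, n_surrogates = 100, bins = 90,
                    working_rate = 1, band_search = c(0.15, 0.4),
                    seed = NULL) {
  if (is.character(study)) study <- load_study(study)
  stopifnot(inherits(study, "study_dataset"))
  cfg <- study$config
  seed <- seed %||% cfg$seed
  fs <- 1 / cfg$sampling_interval

  scores <- behavior_scores(study$trials)
  summary_tbl <- behavior_summary(scores)

  phys <- physio_measures(study)
  saa_delta <- delta_saa(study$saa)

  keys <- dplyr::distinct(study$roi, .data$subject, .data$stage)
  profiles <- purrr::map_dfr(seq_len(nrow(keys)), function(k) {
    subj <- keys$subject[k]; stage <- keys$stage[k]
    series <- phys$series[[paste(subj, stage, sep = "|")]]
    if (is.null(series)) return(NULL)
    r <- dplyr::filter(study$roi, .data$subject == subj, .data$stage == !!stage)
    sm <- cross_spectra(
      tibble::tibble(time = r$time, lc = r$lc, hrv = series$value[seq_len(nrow(r))]),
      fs = fs, bins = bins, working_rate = working_rate)
    dplyr::mutate(coherence_profile(sm, "lc", "hrv"),
                  subject = subj, stage = stage, .before = 1)
  })

  # The coherence peak is sought inside the HF-HRV band (parasympathetic
  # influence on heart rate, 0.15-0.4 Hz) capped at the native Nyquist.
  band <- band_of_max_coherence(
    dplyr::filter(profiles, .data$stage == cfg$stages[1]),
    n_boot = n_boot, seed = child_seed(seed, "band"),
    fmin = band_search[1], fmax = min(band_search[2], fs / 2))

  band_medians <- profiles |>
    dplyr::group_by(.data$subject, .data$stage) |>
    dplyr::group_modify(~ band_summary(.x, band)) |>
    dplyr::ungroup()

  lc_var <- study$roi |>
    dplyr::group_by(.data$subject, .data$stage) |>
    dplyr::summarise(lc_variance = var(.data$lc), .groups = "drop")

  measures <- phys$measures |>
    dplyr::left_join(saa_delta, by = c("subject", "stage")) |>
    dplyr::left_join(lc_var, by = c("subject", "stage")) |>
    dplyr::left_join(band_medians, by = c("subject", "stage")) |>
    dplyr::rename(band_msc = "median_msc", band_phase = "median_phase")

  # AR(1)-surrogate test of LC-HRV band coherence, per stage
  coh_tests <- purrr::map_dfr(cfg$stages, function(stage) {
    subj_rows <- dplyr::filter(measures, .data$stage == !!stage, .data$usable)
    nulls <- vapply(subj_rows$subject, function(subj) {
      series <- phys$series[[paste(subj, stage, sep = "|")]]
      r <- dplyr::filter(study$roi, .data$subject == subj, .data$stage == !!stage)
      nl <- coherence_null(r$lc, series$value[seq_len(nrow(r))], band,
                           n_surrogates = n_surrogates,
                           seed = child_seed(seed, subj, stage, "null"),
                           fs = fs, bins = bins, working_rate = working_rate)
      median(nl$null)
    }, numeric(1))
    res <- partial_coherence_test(subj_rows$band_msc, nulls)
    dplyr::mutate(res, stage = stage, .before = 1)
  })

  # Partial coherence LC-amygdala conditioned on hippocampus, with its
  # surrogate-triple null, per stage
  partial_tests <- purrr::map_dfr(cfg$stages, function(stage) {
    rs <- dplyr::filter(study$roi, .data$stage == !!stage)
    subs <- unique(rs$subject)
    obs <- vapply(subs, function(subj) {
      r <- dplyr::filter(rs, .data$subject == subj)
      sm <- cross_spectra(
        tibble::tibble(time = r$time, lc = r$lc, amygdala = r$amygdala,
                       hippocampus = r$hippocampus),
        fs = fs, bins = bins, working_rate = working_rate)
      pc <- partial_coherence(sm, "lc", "amygdala", "hippocampus")
      band_summary(pc, band)$median_msc
    }, numeric(1))
    nulls <- vapply(subs, function(subj) {
      r <- dplyr::filter(rs, .data$subject == subj)
      median(partial_coherence_null(
        r$lc, r$amygdala, r$hippocampus, band, n_surrogates = n_surrogates,
        seed = child_seed(seed, subj, stage, "pnull"), fs = fs, bins = bins,
        working_rate = working_rate))
    }, numeric(1))
    res <- partial_coherence_test(obs, nulls)
    dplyr::mutate(res, stage = stage,
                  median_observed = median(obs, na.rm = TRUE),
                  median_null = median(nulls, na.rm = TRUE), .before = 1)
  })

  adj <- dplyr::distinct(scores, .data$subject, .data$adjusted_score)
  meas_adj <- dplyr::left_join(measures, adj, by = "subject")

  rm_saa_rmssd <- rmcorr_bootstrap(
    rmcorr(measures, "delta_saa", "rmssd"),
    n_boot = n_boot, seed = child_seed(seed, "rm1"))
  rm_lcvar_rmssd <- rmcorr_bootstrap(
    rmcorr(measures, "lc_variance", "rmssd"),
    n_boot = n_boot, seed = child_seed(seed, "rm2"))
  rm_coh_saa <- rmcorr_bootstrap(
    rmcorr(measures, "band_msc", "delta_saa"),
    n_boot = n_boot, seed = child_seed(seed, "rm3"))

  consol <- dplyr::filter(meas_adj, .data$stage == "consolidation")
  pearson_saa_memory <- pearson_assoc(consol, "delta_saa", "adjusted_score")

  lmm_saa <- stage_lmm(measures, "delta_saa")
  lmm_rmssd <- stage_lmm(measures, "rmssd")
  tukey_saa <- marginal_contrasts(lmm_saa, "stage")
  tukey_rmssd <- marginal_contrasts(lmm_rmssd, "stage")

  lmm_coh <- stage_lmm(dplyr::filter(profiles, !is.na(.data$msc)),
                       outcome = "msc", predictor = "frequency",
                       stage = "stage", interaction = TRUE)
  ros <- region_of_significance(lmm_coh, moderator = "frequency")

  assoc <- tibble::tibble(
    association = c("delta_saa~rmssd", "lc_variance~rmssd",
                    "band_msc~delta_saa", "delta_saa~memory (consolidation)"),
    estimate = c(rm_saa_rmssd$r, rm_lcvar_rmssd$r, rm_coh_saa$r,
                 pearson_saa_memory$r),
    p_value = c(rm_saa_rmssd$p_value, rm_lcvar_rmssd$p_value,
                rm_coh_saa$p_value, pearson_saa_memory$p_value)
  )
  assoc$p_fdr <- fdr_adjust(assoc$p_value)

  structure(
    list(
      behavior = scores, behavior_summary = summary_tbl,
      stage_measures = meas_adj, profiles = profiles, band = band,
      coherence_tests = coh_tests, partial_tests = partial_tests,
      rmcorr = list(saa_rmssd = rm_saa_rmssd, lcvar_rmssd = rm_lcvar_rmssd,
                    coherence_saa = rm_coh_saa),
      pearson = pearson_saa_memory,
      lmm = list(delta_saa = lmm_saa, rmssd = lmm_rmssd,
                 coherence = lmm_coh),
      tukey = list(delta_saa = tukey_saa, rmssd = tukey_rmssd),
      region_of_significance = ros,
      associations = assoc,
      provenance = list(seed = seed,
                        config_hash = rlang::hash(unclass(cfg)),
                        n_boot = n_boot, n_surrogates = n_surrogates)
    ),
    class = "lc_report"
  )
}

#' @export
print.lc_report <- function(x, ...) {
  cat("<lc_report>\n")
  cat(sprintf("  band of max coherence: %.3f Hz [%.3f, %.3f]\n",
              x$band$median, x$band$lower, x$band$upper))
  cat("  associations:\n")
  print(x$associations)
  invisible(x)
}
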