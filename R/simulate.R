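# Synthetic-data module: study-shaped datasets with known ground truth.
#
# Every generator takes an explicit seed (or derives child seeds from the
# cohort seed via child_seed()) so that any subset of a study can be
# regenerated independently and byte-identically.

DEFAULT_STAGES <- c("baseline", "encoding", "consolidation", "recollection")

# sAA sampling schedule: seven swabs across the session.
SAA_SCHEDULE <- c(
  "pre_bore", "pre_baseline", "pre_encoding", "post_encoding",
  "pre_recollection", "post_recollection", "post_30min"
)

#' Cohort-level simulation configuration
#'
#' Describes the shape of a simulated study: number of subjects, the ordered
#' task stages, the BOLD/HRV sampling interval (the scanner TR, 2 s by
#' default) and the number of equidistant samples per stage (240 samples =
#' 8 min at TR 2 s).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param stages Ordered, unique stage labels.
#' @param sampling_interval Seconds per sample (> 0).
#' @param series_length Samples per stage.
#' @param seed Integer seed; all per-subject randomness derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 24, stages = DEFAULT_STAGES,
                          sampling_interval = 2, series_length = 240,
                          seed = 1L) {
  assert_that(is_count(n_subjects), "n_subjects must be a positive integer")
  assert_that(length(stages) >= 1 && !anyDuplicated(stages),
              "stages must be non-empty and unique")
  assert_that(is.numeric(sampling_interval) && sampling_interval > 0,
              "sampling_interval must be > 0")
  assert_that(is_count(series_length), "series_length must be a positive integer")
  structure(
    list(n_subjects = as.integer(n_subjects), stages = as.character(stages),
         sampling_interval = sampling_interval,
         series_length = as.integer(series_length), seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Band-limited coupling specification for a pair of series
#'
#' Ground truth for coherence-recovery experiments: two series share a
#' band-limited latent component (one copy phase-shifted), on top of
#' independent AR(1) noise. The mixing weight is solved analytically so
#' the theoretical magnitude-squared coherence at `band_center` equals
#' `target_msc` (see [simulate_coupled_series()]).
#'
#' @param band_center,band_width Coupling band (Hz); must lie strictly
#'   inside (0, Nyquist) for the cohort sampling rate.
#' @param target_msc Target magnitude-squared coherence in `[0, 1]`.
#' @param target_phase Phase lag (radians, `(-pi, pi]`); positive means the
#'   first series leads.
#' @param ar1_coefficient Lag-1 coefficient of the additive noise, |phi| < 1.
#' @param noise_sd Marginal standard deviation of the AR(1) noise.
#' @param band_shape `"peaked"` (default): the coupling strength follows a
#'   Gaussian profile centered on `band_center` (sd = `band_width/4`,
#'   truncated at the band edges), so `target_msc` holds at the center and
#'   coherence falls off toward the edges -- a unimodal profile with a
#'   well-defined peak frequency, as in physiological coupling.
#'   `"flat"`: the theoretical MSC equals `target_msc` at every in-band
#'   frequency (useful for analytic calibration of the magnitude).
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(band_center = 0.2, band_width = 0.05,
                          target_msc = 0.7, target_phase = 0,
                          ar1_coefficient = 0.3, noise_sd = 1,
                          band_shape = c("peaked", "flat")) {
  band_shape <- match.arg(band_shape)
  assert_that(is_prob(target_msc), "target_msc must lie in [0, 1]")
  assert_that(abs(ar1_coefficient) < 1, "|ar1_coefficient| must be < 1")
  assert_that(target_phase > -pi && target_phase <= pi + 1e-12,
              "target_phase must lie in (-pi, pi]")
  assert_that(band_center - band_width / 2 > 0,
              "band must lie strictly above 0 Hz")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(
    list(band_center = band_center, band_width = band_width,
         target_msc = target_msc, target_phase = target_phase,
         ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
         band_shape = band_shape),
    class = "coupling_spec"
  )
}

#' Behavioral ground-truth specification
#'
#' Trial structure and equal-variance Gaussian SDT parameters per valence.
#' Defaults mirror the face-name paradigm: 45 old faces per valence at
#' encoding, 23 emotional + 22 neutral new faces at recognition, and
#' sensitivity/criterion values typical of young-adult cohorts on this task.
#'
#' @param n_old_per_valence Old (studied) trials per valence; scalar or
#'   named per-valence vector.
#' @param n_new_per_valence New (lure) trials per valence.
#' @param dprime_by_valence Named per-valence d-prime.
#' @param criterion_by_valence Named per-valence criterion c.
#' @param recollection_prob_by_valence P(correct name | hit), per valence.
#' @return A `behavior_spec` list with per-valence vectors.
#' @export
behavior_spec <- function(n_old_per_valence = 45,
                          n_new_per_valence = c(emotional = 23, neutral = 22),
                          dprime_by_valence = c(emotional = 0.83, neutral = 1.18),
                          criterion_by_valence = c(emotional = 0.33, neutral = 0.51),
                          recollection_prob_by_valence = c(emotional = 0.50, neutral = 0.45)) {
  valences <- names(dprime_by_valence) %||% c("emotional", "neutral")
  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) x <- setNames(rep(x, length(valences)), valences)
    assert_that(all(valences %in% names(x)),
                paste0(what, " must be named for every valence"))
    x[valences]
  }
  n_old <- expand(n_old_per_valence, "n_old_per_valence")
  n_new <- expand(n_new_per_valence, "n_new_per_valence")
  rec_p <- expand(recollection_prob_by_valence, "recollection_prob_by_valence")
  assert_that(all(n_old >= 1) && all(n_new >= 1), "trial counts must be positive")
  assert_that(is_prob(rec_p), "recollection probabilities must lie in [0, 1]")
  structure(
    list(valences = valences, n_old = n_old, n_new = n_new,
         dprime = expand(dprime_by_valence, "dprime_by_valence"),
         criterion = expand(criterion_by_valence, "criterion_by_valence"),
         recollection_prob = rec_p),
    class = "behavior_spec"
  )
}

#' Simulate a behavioral trial table under the equal-variance SDT model
#'
#' For each old trial the latent familiarity is N(d', 1), for each new trial
#' N(0, 1); the face is endorsed ("recognized") when familiarity exceeds the
#' decision threshold k = c + d'/2, which reproduces hit rate
#' Phi(d'/2 - c) and false-alarm rate Phi(-d'/2 - c). Given a hit, the
#' correct name is chosen with the per-valence recollection probability;
#' recollection is undefined (NA) for unendorsed or new trials.
#'
#' @param config A [cohort_config()].
#' @param spec A [behavior_spec()].
#' @return A tibble with one row per subject x trial: `subject`, `valence`,
#'   `is_old`, `recognized`, `recollected_correct`, `rt_recognition`,
#'   `rt_recollection`.
#' @export
simulate_behavior <- function(config, spec = behavior_spec()) {
  stopifnot(inherits(config, "cohort_config"), inherits(spec, "behavior_spec"))
  one_subject <- function(subj) {
    with_seed(child_seed(config$seed, subj, "behavior"), {
      purrr::map_dfr(spec$valences, function(v) {
        n_old <- spec$n_old[[v]]; n_new <- spec$n_new[[v]]
        k <- spec$criterion[[v]] + spec$dprime[[v]] / 2
        fam <- c(rnorm(n_old, mean = spec$dprime[[v]]), rnorm(n_new, mean = 0))
        is_old <- rep(c(TRUE, FALSE), c(n_old, n_new))
        recog <- fam > k
        recol <- ifelse(is_old & recog,
                        runif(n_old + n_new) < spec$recollection_prob[[v]], NA)
        tibble::tibble(
          subject = subj, valence = v, is_old = is_old, recognized = recog,
          recollected_correct = as.logical(recol),
          rt_recognition = rlnorm(n_old + n_new, log(1.5), 0.22),
          rt_recollection = ifelse(recog, rlnorm(n_old + n_new, log(1.9), 0.20), NA_real_)
        )
      })
    })
  }
  purrr::map_dfr(sprintf("s%02d", seq_len(config$n_subjects)), one_subject)
}

#' Simulate a pulse-oximeter beat timeline with controllable artifacts
#'
#' Clean R-R intervals are i.i.d. Gaussian (so the ground-truth rMSSD is
#' `rr_sd_ms * sqrt(2)` in the large-sample limit). Artifacts are spurious
#' extra beats inserted a quarter of the way into a fraction `artifact_rate`
#' of the intervals, producing implausibly fast instantaneous rates that the
#' cleaning step should remove. The clean timeline is retained for oracle
#' comparisons.
#'
#' @param config A [cohort_config()]; stage duration
#'   (`series_length * sampling_interval`) sets the timeline length.
#' @param mean_rr_ms,rr_sd_ms Mean and SD of the clean R-R intervals (ms).
#' @param artifact_rate Fraction of intervals receiving a spurious beat.
#' @param seed Integer seed.
#' @param rr_series Optional numeric vector of additive per-beat R-R
#'   modulation (ms) evaluated on the cumulative beat grid; used internally
#'   to imprint a coupled HRV fluctuation onto the beats.
#' @return A list of class `beat_timeline`: `beats` (tibble with `time` in s
#'   and `is_artifact`), `clean` (artifact-free tibble), `rr_clean_ms`.
#' @export
simulate_beats <- function(config, mean_rr_ms = 1000, rr_sd_ms = 30,
                           artifact_rate = 0, seed = config$seed,
                           rr_series = NULL) {
  assert_that(mean_rr_ms >= 300 && mean_rr_ms <= 2400,
              "mean_rr_ms outside the physiological band")
  assert_that(is_prob(artifact_rate), "artifact_rate must lie in [0, 1]")
  duration <- config$series_length * config$sampling_interval
  n_beats <- ceiling(duration / (mean_rr_ms / 1000)) + 2L
  with_seed(seed, {
    rr <- rnorm(n_beats, mean_rr_ms, rr_sd_ms)
    if (!is.null(rr_series)) {
      rr <- rr + rr_series[pmin(seq_along(rr), length(rr_series))]
    }
    rr <- pmax(rr, 0.3 * mean_rr_ms) # keep intervals physiological
    t_clean <- cumsum(rr) / 1000
    keep <- t_clean <= duration
    t_clean <- t_clean[keep]; rr <- rr[keep]
    spurious <- which(runif(length(t_clean) - 1) < artifact_rate)
    # insert an extra beat 25% into the chosen intervals: the implied
    # instantaneous rate is ~4x the rhythm, beyond the 200 bpm bound
    t_extra <- t_clean[spurious] + 0.25 * diff(t_clean)[spurious]
    beats <- tibble::tibble(
      time = c(t_clean, t_extra),
      is_artifact = rep(c(FALSE, TRUE), c(length(t_clean), length(t_extra)))
    )
    beats <- dplyr::arrange(beats, .data$time)
    structure(
      list(beats = beats, clean = tibble::tibble(time = t_clean),
           rr_clean_ms = rr, duration = duration),
      class = "beat_timeline"
    )
  })
}

# Theoretical two-sided PSD of an AR(1) process with marginal sd `sd` and
# coefficient `phi`, sampled every `dt` seconds, evaluated at frequency f.
ar1_psd <- function(f, phi, sd, dt) {
  sd^2 * (1 - phi^2) * dt / Mod(1 - phi * exp(-2i * pi * f * dt))^2
}

# Zero-phase band-limited latent: white noise masked in the frequency
# domain (an ideal band-pass, exactly zero phase distortion), with an
# optional real amplitude weighting w(f) inside the band. Returns the
# complex spectrum so that a constant phase shift can be applied exactly
# before transforming back.
band_limited_latent <- function(n, fs, band_center, band_width, weight = NULL) {
  z <- rnorm(n)
  zf <- fft(z)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n # two-sided |frequency|
  mask <- freq >= band_center - band_width / 2 & freq <= band_center + band_width / 2
  zf[!mask] <- 0
  if (!is.null(weight)) zf[mask] <- zf[mask] * weight(freq[mask])
  zf
}

# Apply a constant phase delay `theta` to the positive-frequency half of a
# spectrum (conjugate-symmetric on the negative half so the signal stays
# real), then invert.
shift_phase <- function(zf, theta) {
  n <- length(zf)
  k <- 0:(n - 1)
  pos <- k >= 1 & k < n / 2
  neg <- k > n / 2
  rot <- rep(1 + 0i, n)
  rot[pos] <- exp(-1i * theta)
  rot[neg] <- exp(1i * theta)
  Re(fft(zf * rot, inverse = TRUE)) / n
}

# Simulate a stationary AR(1) series (marginal sd `sd`) with burn-in.
sim_ar1 <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- as.numeric(stats::filter(rnorm(n + 200, 0, innov_sd), phi, method = "recursive"))
  x[(length(x) - n + 1):length(x)]
}

#' Simulate a pair of series with known band-limited coherence and phase
#'
#' Both series share a band-limited latent component `s` (unit variance,
#' built by ideal zero-phase band-pass filtering of white noise); the second
#' series carries a copy phase-delayed by `target_phase` applied exactly in
#' the frequency domain. Independent AR(1) noise is added to each channel.
#'
#' The mixing weight `a` follows in closed form from the MSC definition.
#' With latent two-sided PSD S(f) and noise PSD N(f) on both channels, the
#' theoretical coherence at f is
#'   MSC(f) = ( a^2 S(f) / (a^2 S(f) + N(f)) )^2.
#' The latent spectrum is shaped proportional to sqrt(G(f) N(f)) inside the
#' band, where G is the band-shape gain (identically 1 for `"flat"`, a
#' truncated Gaussian with sd `band_width/4` for `"peaked"`). After
#' unit-variance normalisation S(f) = G(f) N(f) / V with
#' V = integral of G N over the band (both sides), so
#' a^2 S / N = a^2 G / V and solving at the band center (G = 1):
#'   a^2 = V * rho / (1 - rho),  rho = sqrt(target_msc).
#' For `"flat"` the target then holds at every in-band frequency; for
#' `"peaked"` it holds at the center and tapers toward the edges.
#' `target_msc = 1` requires `noise_sd = 0`; `target_msc < 1` with zero
#' noise is infeasible and raises an error.
#'
#' @param config A [cohort_config()] (gives sampling interval and length).
#' @param spec A [coupling_spec()].
#' @param seed Integer seed.
#' @return A tibble `time`, `x`, `y` (x leads y by `target_phase` at the
#'   band center) with the spec attached as attribute `ground_truth`.
#' @export
simulate_coupled_series <- function(config, spec, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"), inherits(spec, "coupling_spec"))
  fs <- 1 / config$sampling_interval
  nyq <- fs / 2
  assert_that(spec$band_center + spec$band_width / 2 < nyq,
              "coupling band must lie below the Nyquist frequency")
  n <- config$series_length
  m <- spec$target_msc
  if (m == 1 && spec$noise_sd > 0)
    abort("target_msc = 1 is infeasible with noise_sd > 0",
          class = "lcarousal_config_error")
  if (m < 1 && spec$noise_sd == 0)
    abort("target_msc < 1 is infeasible with noise_sd = 0 (coherence is 1 by construction)",
          class = "lcarousal_config_error")
  gain <- if (identical(spec$band_shape, "flat")) {
    function(f) rep(1, length(f))
  } else {
    function(f) exp(-(f - spec$band_center)^2 / (2 * (spec$band_width / 4)^2))
  }
  with_seed(seed, {
    weight <- if (spec$noise_sd > 0) {
      function(f) sqrt(gain(f) * ar1_psd(f, spec$ar1_coefficient, spec$noise_sd,
                                         config$sampling_interval))
    } else {
      function(f) sqrt(gain(f))
    }
    zf <- band_limited_latent(n, fs, spec$band_center, spec$band_width, weight)
    s_x <- Re(fft(zf, inverse = TRUE)) / n
    s_y <- shift_phase(zf, spec$target_phase)
    norm <- sd(s_x)
    if (norm > 0) { s_x <- s_x / norm; s_y <- s_y / norm }
    if (spec$noise_sd == 0) {
      a <- 1
      n1 <- n2 <- numeric(n)
    } else {
      rho <- sqrt(m)
      # V = integral of G(f) N(f) over the (two-sided) coupling band
      half <- spec$band_width / 2
      fgrid <- seq(spec$band_center - half, spec$band_center + half,
                   length.out = 201)
      V <- 2 * sum(gain(fgrid) *
                     ar1_psd(fgrid, spec$ar1_coefficient, spec$noise_sd,
                             config$sampling_interval)) * diff(fgrid)[1]
      a <- sqrt(V * rho / (1 - rho))
      n1 <- sim_ar1(n, spec$ar1_coefficient, spec$noise_sd)
      n2 <- sim_ar1(n, spec$ar1_coefficient, spec$noise_sd)
    }
    out <- tibble::tibble(
      time = (seq_len(n) - 1) * config$sampling_interval,
      x = a * s_x + n1, y = a * s_y + n2
    )
    attr(out, "ground_truth") <- spec
    out
  })
}

#' Simulate a complete multi-stage study dataset with ground truth
#'
#' Bundles everything the downstream pipeline consumes: the behavioral trial
#' table, per-subject/per-stage beat timelines, ROI BOLD series (LC,
#' reference, amygdala, hippocampus, entorhinal), and the seven-sample sAA
#' schedule. The LC series and the heart-beat stream are coupled per the
#' stage's [coupling_spec()]: the HRV-partner series is integrated into the
#' R-R interval sequence so that the successive-difference series recovered
#' by the preprocessing pipeline carries the specified coherence with the LC
#' channel. sAA values follow a log-normal noise model (sAA is non-negative
#' and right-skewed) around a deterministic stage path whose increments are
#' the per-stage `saa_effects`.
#'
#' @param config A [cohort_config()].
#' @param coupling_by_stage Named list: one [coupling_spec()] per stage.
#' @param behavior A [behavior_spec()].
#' @param saa_effects Named numeric: expected sAA end-minus-beginning change
#'   (U/ml) for each stage.
#' @param mean_rr_ms,rr_jitter_ms,artifact_rate Beat-generation parameters;
#'   `hrv_scale_ms` scales the coupled HRV fluctuation imprinted on the R-R
#'   differences.
#' @param saa_base,saa_log_sd Baseline sAA level (U/ml) and log-scale noise SD.
#' @return A `study_dataset` list: `trials`, `beats`, `roi`, `saa`, `config`,
#'   `ground_truth`.
#' @export
simulate_study <- function(config = cohort_config(),
                           coupling_by_stage = NULL,
                           behavior = behavior_spec(),
                           saa_effects = c(baseline = 0, encoding = 10,
                                           consolidation = 60, recollection = 10),
                           mean_rr_ms = 1000, rr_jitter_ms = 4,
                           artifact_rate = 0.02, hrv_scale_ms = 30,
                           saa_base = 60, saa_log_sd = 0.1) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(coupling_by_stage)) {
    coupling_by_stage <- setNames(
      lapply(config$stages, function(s) coupling_spec()), config$stages)
  }
  assert_that(setequal(names(coupling_by_stage), config$stages),
              "coupling_by_stage must name exactly the configured stages")
  assert_that(setequal(config$stages, DEFAULT_STAGES),
              "simulate_study() requires the four canonical task stages (baseline, encoding, consolidation, recollection); the seven-sample sAA schedule is tied to them")
  assert_that(all(config$stages %in% names(saa_effects)) ||
                length(saa_effects) == length(config$stages),
              "saa_effects must cover every stage")
  if (is.null(names(saa_effects))) names(saa_effects) <- config$stages

  subjects <- sprintf("s%02d", seq_len(config$n_subjects))
  trials <- simulate_behavior(config, behavior)

  n <- config$series_length
  dt <- config$sampling_interval
  grid <- (seq_len(n) - 1) * dt

  per_subject_stage <- function(subj, stage) {
    cs <- coupling_by_stage[[stage]]
    pair <- simulate_coupled_series(config, cs,
                                    seed = child_seed(config$seed, subj, stage, "pair"))
    with_seed(child_seed(config$seed, subj, stage, "roi"), {
      roi <- tibble::tibble(
        subject = subj, stage = stage, time = grid,
        lc = pair$x,
        reference = sim_ar1(n, cs$ar1_coefficient, 1),
        amygdala = sim_ar1(n, cs$ar1_coefficient, 1),
        hippocampus = sim_ar1(n, cs$ar1_coefficient, 1),
        entorhinal = sim_ar1(n, cs$ar1_coefficient, 1)
      )
    })
    # Imprint the coupled partner on the R-R stream: RR_k = mean + scale *
    # cumsum(y(t_k)), so successive R-R differences recover scale * y at the
    # beat times and the pipeline-derived HRV series inherits the target
    # coherence with the LC channel (MSC is invariant to the scale). The
    # partner is high-passed below the coupling band first: cumulative
    # summation amplifies low frequencies as 1/(2 pi f), so residual noise
    # power near DC would otherwise random-walk the R-R baseline; in-band
    # content (hence the target coherence) is untouched.
    f_hp <- 0.5 * (cs$band_center - cs$band_width / 2)
    yf <- fft(pair$y)
    kk <- 0:(n - 1)
    fgrid <- pmin(kk, n - kk) / (n * dt)
    yf[fgrid < f_hp] <- 0
    y_hp <- Re(fft(yf, inverse = TRUE)) / n
    y_fun <- splinefun(pair$time, y_hp, method = "fmm")
    approx_beat_times <- cumsum(rep(mean_rr_ms / 1000,
                                    ceiling(n * dt / (mean_rr_ms / 1000)) + 2))
    rr_mod <- hrv_scale_ms * cumsum(y_fun(pmin(approx_beat_times, max(grid))))
    rr_mod <- rr_mod - mean(rr_mod)
    bt <- simulate_beats(config, mean_rr_ms, rr_jitter_ms, artifact_rate,
                         seed = child_seed(config$seed, subj, stage, "beats"),
                         rr_series = rr_mod)
    list(roi = roi,
         beats = dplyr::mutate(bt$beats, subject = subj, stage = stage,
                               .before = 1))
  }

  pieces <- purrr::map(subjects, function(subj) {
    st <- purrr::map(config$stages, function(stage) per_subject_stage(subj, stage))
    list(roi = purrr::map_dfr(st, "roi"), beats = purrr::map_dfr(st, "beats"))
  })

  saa <- purrr::map_dfr(subjects, function(subj) {
    with_seed(child_seed(config$seed, subj, "saa"), {
      eff <- saa_effects[config$stages]
      path <- c(
        pre_bore = saa_base,
        pre_baseline = saa_base,
        pre_encoding = saa_base + eff[["baseline"]],
        post_encoding = saa_base + eff[["baseline"]] + eff[["encoding"]],
        pre_recollection = saa_base + eff[["baseline"]] + eff[["encoding"]] +
          eff[["consolidation"]],
        post_recollection = saa_base + sum(eff),
        post_30min = saa_base
      )
      path <- pmax(path, 1)
      tibble::tibble(subject = subj, label = names(path),
                     value = unname(path * rlnorm(length(path), 0, saa_log_sd)))
    })
  })

  structure(
    list(trials = trials,
         beats = purrr::map_dfr(pieces, "beats"),
         roi = purrr::map_dfr(pieces, "roi"),
         saa = saa,
         config = config,
         ground_truth = list(coupling_by_stage = coupling_by_stage,
                             behavior = behavior, saa_effects = saa_effects,
                             mean_rr_ms = mean_rr_ms, rr_jitter_ms = rr_jitter_ms,
                             artifact_rate = artifact_rate,
                             hrv_scale_ms = hrv_scale_ms)),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>\n")
  cat("  subjects:", x$config$n_subjects,
      " stages:", paste(x$config$stages, collapse = ", "), "\n")
  cat("  trials:", nrow(x$trials), " beats:", nrow(x$beats),
      " roi samples:", nrow(x$roi), " saa samples:", nrow(x$saa), "\n")
  invisible(x)
}
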