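# Physiological module: beat cleaning, HRV series, rMSSD, sAA deltas,
# exclusion rules and arousal regressors.

#' Clean a pulse-oximeter beat timeline
#'
#' Two rejection rules act on the instantaneous rate implied by each
#' inter-beat interval, measured against the last accepted beat:
#' \itemize{
#'   \item absolute bounds: rates outside `[min_bpm, max_bpm]` (25-200 bpm
#'     by default) are physiologically implausible;
#'   \item adaptive rule: rates deviating by more than `rel_threshold`
#'     (13\% by default) from the running mean of the last `window`
#'     accepted intervals.
#' }
#' Implausibly fast intervals mark a spurious beat: the beat is removed and
#' the anchor stays at the last accepted beat. Implausibly slow intervals
#' mark missing beats (a gap): the segment is flagged as missing signal but
#' the terminating beat is kept as the new anchor -- deleting it would only
#' lengthen the gap and cascade into rejecting the rest of the recording.
#' Gap segments feed the percent-missing exclusion rule and are excluded
#' from R-R statistics. The procedure is idempotent.
#'
#' @param beats Numeric vector of beat timestamps (s), or a tibble/data
#'   frame with a `time` column, or a `beat_timeline`.
#' @param min_bpm,max_bpm Physiological rate bounds.
#' @param rel_threshold Relative deviation from the running mean that
#'   triggers the adaptive rule.
#' @param window Number of most recent accepted intervals in the running mean.
#' @return A list of class `beat_cleaning`: `beats` (tibble `time`),
#'   `intervals` (tibble `t_start`, `t_end`, `rr_ms`, `status`
#'   accepted/gap), `gaps`, and a rejection `report`.
#' @export
clean_beats <- function(beats, min_bpm = 25, max_bpm = 200,
                        rel_threshold = 0.13, window = 10) {
  t <- beat_times(beats)
  assert_that(length(t) >= 2, "need at least 2 beats")
  assert_that(all(diff(t) > 0), "beat timestamps must be strictly increasing")

  kept <- t[1]
  intervals <- list()
  rates <- numeric(0) # accepted instantaneous rates (bpm)
  n_bounds <- 0L; n_adaptive <- 0L; n_gaps <- 0L
  last <- t[1]
  for (i in seq_along(t)[-1]) {
    iv <- t[i] - last
    bpm <- 60 / iv
    run_mean <- if (length(rates) > 0) mean(tail(rates, window)) else NA_real_
    too_fast <- bpm > max_bpm ||
      (!is.na(run_mean) && bpm > run_mean * (1 + rel_threshold))
    too_slow <- bpm < min_bpm ||
      (!is.na(run_mean) && bpm < run_mean * (1 - rel_threshold))
    if (too_fast) {
      # spurious beat: drop it, keep the anchor
      if (bpm > max_bpm) n_bounds <- n_bounds + 1L else n_adaptive <- n_adaptive + 1L
    } else if (too_slow) {
      # missing beats: flag the segment, keep the beat as the new anchor
      if (bpm < min_bpm) n_bounds <- n_bounds + 1L else n_adaptive <- n_adaptive + 1L
      n_gaps <- n_gaps + 1L
      intervals[[length(intervals) + 1]] <-
        list(t_start = last, t_end = t[i], rr_ms = iv * 1000, status = "gap")
      kept <- c(kept, t[i]); last <- t[i]
    } else {
      intervals[[length(intervals) + 1]] <-
        list(t_start = last, t_end = t[i], rr_ms = iv * 1000, status = "accepted")
      rates <- c(rates, bpm)
      kept <- c(kept, t[i]); last <- t[i]
    }
  }
  if (length(kept) < 2) {
    abort("fewer than 2 beats survive cleaning; stage unusable",
          class = "lcarousal_unusable_error")
  }
  ivt <- dplyr::bind_rows(lapply(intervals, tibble::as_tibble))
  structure(
    list(
      beats = tibble::tibble(time = kept),
      intervals = ivt,
      gaps = dplyr::filter(ivt, .data$status == "gap"),
      report = tibble::tibble(
        n_input = length(t), n_kept = length(kept),
        n_rejected_bounds = n_bounds, n_rejected_adaptive = n_adaptive,
        n_gap_segments = n_gaps
      )
    ),
    class = "beat_cleaning"
  )
}

beat_times <- function(beats) {
  if (inherits(beats, "beat_timeline")) return(beats$beats$time)
  if (inherits(beats, "beat_cleaning")) return(beats$beats$time)
  if (is.data.frame(beats)) return(beats$time)
  as.numeric(beats)
}

# Successive R-R differences on contiguous accepted intervals: pairs of
# adjacent accepted intervals that share an endpoint (no gap in between).
successive_rr_diffs <- function(cleaned) {
  iv <- cleaned$intervals
  acc <- iv$status == "accepted"
  contiguous <- acc[-1] & acc[-nrow(iv)] &
    (iv$t_start[-1] == iv$t_end[-nrow(iv)])
  tibble::tibble(
    time = iv$t_end[-1][contiguous],
    diff_ms = (iv$rr_ms[-1] - iv$rr_ms[-nrow(iv)])[contiguous]
  )
}

#' Interpolate the successive R-R difference series onto an equidistant grid
#'
#' The HRV series is the sequence of successive R-R interval differences
#' (ms), placed at the time of the later beat and cubic-spline interpolated
#' onto the grid `0, dt, 2 dt, ...`. Grid points falling inside flagged
#' gap segments, or outside the span of observed beats, are recorded as
#' missing signal (the values are still interpolated so the series stays
#' equidistant; the missing fraction drives the exclusion rule).
#'
#' @param cleaned A [clean_beats()] result (or a raw timeline, cleaned with
#'   defaults first).
#' @param sampling_interval Grid spacing dt (s), typically the TR.
#' @param duration Total series duration (s); defaults to the last beat time.
#' @return Tibble of class `hrv_series`: `time`, `value` (ms), `missing`
#'   (logical), with attributes `percent_missing` and `sampling_interval`.
#' @export
interpolate_hrv <- function(cleaned, sampling_interval, duration = NULL) {
  if (!inherits(cleaned, "beat_cleaning")) cleaned <- clean_beats(cleaned)
  knots <- successive_rr_diffs(cleaned)
  assert_that(nrow(knots) >= 4,
              "cubic interpolation needs at least 4 R-R difference points")
  duration <- duration %||% max(cleaned$beats$time)
  grid <- seq(0, duration, by = sampling_interval)
  f <- splinefun(knots$time, knots$diff_ms, method = "fmm")
  missing <- rep(FALSE, length(grid))
  if (nrow(cleaned$gaps) > 0) {
    for (g in seq_len(nrow(cleaned$gaps))) {
      missing <- missing |
        (grid > cleaned$gaps$t_start[g] & grid < cleaned$gaps$t_end[g])
    }
  }
  missing <- missing | grid < min(knots$time) | grid > max(knots$time)
  out <- tibble::tibble(time = grid, value = f(grid), missing = missing)
  class(out) <- c("hrv_series", class(out))
  attr(out, "percent_missing") <- 100 * mean(missing)
  attr(out, "sampling_interval") <- sampling_interval
  out
}

#' Root mean square of successive differences (rMSSD)
#'
#' Time-domain vagal-tone index: `sqrt(mean(diff(rr)^2))` over the R-R
#' interval sequence (ms). Computed on raw accepted intervals, never on the
#' interpolated series (interpolation distorts successive differences).
#'
#' @param intervals Numeric R-R intervals (ms), or a [clean_beats()] result
#'   (contiguous accepted intervals are used, gaps are not bridged).
#' @return rMSSD in ms; NA with fewer than 2 intervals.
#' @export
rmssd <- function(intervals) {
  if (inherits(intervals, "beat_cleaning")) {
    d <- successive_rr_diffs(intervals)$diff_ms
  } else {
    intervals <- intervals[!is.na(intervals)]
    if (length(intervals) < 2) return(NA_real_)
    d <- diff(intervals)
  }
  if (length(d) < 1) return(NA_real_)
  sqrt(mean(d^2))
}

#' Stage-wise salivary alpha-amylase change
#'
#' For each task stage, delta-sAA = level at the stage's end minus level at
#' its beginning, using the seven-sample schedule. The default pairing:
#' baseline = pre_baseline to pre_encoding, encoding = pre to post encoding,
#' consolidation = post_encoding to pre_recollection, recollection = pre to
#' post recollection. A missing endpoint propagates to a missing delta.
#'
#' @param saa Tibble `subject`, `label` (schedule point), `value` (U/ml).
#' @param mapping Named list: for each stage, `c(begin_label, end_label)`.
#' @return Tibble `subject`, `stage`, `delta_saa`.
#' @export
delta_saa <- function(saa,
                      mapping = list(
                        baseline = c("pre_baseline", "pre_encoding"),
                        encoding = c("pre_encoding", "post_encoding"),
                        consolidation = c("post_encoding", "pre_recollection"),
                        recollection = c("pre_recollection", "post_recollection"))) {
  known <- unique(c(SAA_SCHEDULE, unlist(mapping)))
  bad <- setdiff(unique(saa$label), known)
  if (length(bad) > 0) {
    abort(paste("unknown sAA schedule label(s):", paste(bad, collapse = ", ")),
          class = "lcarousal_validation_error")
  }
  lookup <- function(subj, lab) {
    v <- saa$value[saa$subject == subj & saa$label == lab]
    if (length(v) == 0) NA_real_ else v[[1]]
  }
  purrr::map_dfr(unique(saa$subject), function(subj) {
    purrr::map_dfr(names(mapping), function(stage) {
      tibble::tibble(
        subject = subj, stage = stage,
        delta_saa = lookup(subj, mapping[[stage]][2]) -
          lookup(subj, mapping[[stage]][1])
      )
    })
  })
}

#' Usability check for an HRV series
#'
#' A stage is usable when at most `max_missing_pct` percent of its time
#' points lack cardiac signal (10\% by default).
#'
#' @param series An `hrv_series` from [interpolate_hrv()], or a percent
#'   missing value.
#' @param max_missing_pct Exclusion threshold (percent).
#' @return Logical.
#' @export
hrv_usable <- function(series, max_missing_pct = 10) {
  pct <- if (is.numeric(series)) series else attr(series, "percent_missing")
  assert_that(is.numeric(pct) && length(pct) == 1, "percent missing unavailable")
  pct <= max_missing_pct
}

#' Arousal events: local HRV minima over a rolling window
#'
#' A sample is an event when it is the strict minimum of the centered
#' rolling window (15 s by default); with tied minima only the earliest
#' sample in the window is flagged. Edge samples without a full centered
#' window are never flagged.
#'
#' @param series An `hrv_series`, or numeric vector (then
#'   `sampling_interval` must be given).
#' @param window Window length (s).
#' @param sampling_interval Grid spacing (s) when `series` is a bare vector.
#' @return Numeric vector of event times (s).
#' @export
local_minima_events <- function(series, window = 15, sampling_interval = NULL) {
  if (inherits(series, "hrv_series")) {
    dt <- attr(series, "sampling_interval")
    x <- series$value; tt <- series$time
  } else {
    dt <- sampling_interval
    assert_that(!is.null(dt), "sampling_interval required for a bare vector")
    x <- as.numeric(series); tt <- (seq_along(x) - 1) * dt
  }
  half <- floor((window / dt) / 2)
  assert_that(2 * half + 1 >= 3, "window must span at least 3 samples")
  n <- length(x)
  if (n < 2 * half + 1) return(numeric(0))
  if (sd(x) == 0) {
    warn("constant HRV series: no local minima events")
    return(numeric(0))
  }
  events <- logical(n)
  for (i in (half + 1):(n - half)) {
    win <- x[(i - half):(i + half)]
    if (x[i] == min(win) && which.min(win) == half + 1) events[i] <- TRUE
  }
  tt[events]
}

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities parameterised by their peak times:
#' response peaking at `peak` s (6 s), undershoot peaking at `undershoot` s
#' (16 s), undershoot amplitude 1/`ratio` (1/6) of the response. Normalised
#' to unit peak amplitude.
#'
#' @param t Time points (s).
#' @param peak,undershoot,ratio,dispersion Shape parameters.
#' @return HRF values at `t`.
#' @export
double_gamma_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6,
                             dispersion = 1) {
  # gamma density with mode m and rate 1/dispersion has shape m/dispersion + 1
  h <- dgamma(t, shape = peak / dispersion + 1, rate = 1 / dispersion) -
    dgamma(t, shape = undershoot / dispersion + 1, rate = 1 / dispersion) / ratio
  h / max(h)
}

#' Event regressor: impulses convolved with the double-gamma HRF
#'
#' Builds a unit-impulse train at the event samples, convolves it with the
#' canonical double-gamma HRF and truncates to the series length.
#'
#' @param events Event times (s), within the series duration.
#' @param series_length Number of samples.
#' @param sampling_interval Grid spacing (s).
#' @param ... Passed to [double_gamma_hrf()].
#' @return Numeric regressor of length `series_length`.
#' @export
hrf_regressor <- function(events, series_length, sampling_interval, ...) {
  duration <- (series_length - 1) * sampling_interval
  assert_that(all(events >= 0 & events <= duration),
              "events must fall within the series duration")
  impulses <- numeric(series_length)
  if (length(events) > 0) {
    idx <- round(events / sampling_interval) + 1
    for (i in idx) impulses[i] <- impulses[i] + 1
  }
  hrf_t <- seq(0, 32, by = sampling_interval)
  kernel <- double_gamma_hrf(hrf_t, ...)
  out <- convolve(impulses, rev(kernel), type = "open")
  out[seq_len(series_length)]
}
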