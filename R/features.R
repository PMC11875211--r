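#' Estimate the FHR baseline
#'
#' Baseline is the modal FHR level excluding transient excursions: the mode
#' of the segment's values binned at 2.5 bpm, refined as the mean of all
#' samples within +/- 10 bpm of the modal bin center.  Accelerations and
#' decelerations occupy a minority of the segment, so the mode is robust to
#' them without needing event detection first.
#'
#' @param fhr complete (cleaned) FHR vector, bpm.
#' @return baseline in bpm.
#' @export
estimate_baseline <- function(fhr) {
  stopifnot(length(fhr) > 0, !anyNA(fhr))
  bins <- round(fhr / 2.5) * 2.5
  tab <- table(bins)
  mode_bin <- as.numeric(names(tab)[which.max(tab)])
  near <- fhr[abs(fhr - mode_bin) <= 10]
  mean(near)
}

#' Detect accelerations
#'
#' Maximal runs with FHR at or above baseline + 15 bpm sustained for at
#' least 15 s (60 samples at 4 Hz).
#'
#' @param fhr complete FHR vector.
#' @param baseline baseline bpm from [estimate_baseline()].
#' @param fs sample rate (Hz).
#' @return event data.frame: `kind, onset_s, end_s, extremum_bpm,
#'   lag_vs_uc_peak_s` (lag is `NA` for accelerations).
#' @export
detect_accelerations <- function(fhr, baseline, fs = 4) {
  runs <- true_runs(fhr >= baseline + 15)
  runs <- runs[runs$length >= 15 * fs, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty_events())
  data.frame(kind = "acceleration",
             onset_s = (runs$start - 1) / fs,
             end_s = runs$end / fs,
             extremum_bpm = vapply(seq_len(nrow(runs)), function(i)
               max(fhr[runs$start[i]:runs$end[i]]), numeric(1)),
             lag_vs_uc_peak_s = NA_real_)
}

#' Detect and type decelerations
#'
#' Maximal runs with FHR at or below baseline - 15 bpm sustained >= 15 s.
#' Typing relative to the nearest smoothed-UC peak, by nadir lag
#' (nadir time minus peak time):
#' * duration >= 120 s: `prolonged_decel` (overrides all other typing);
#' * no contraction peak within 60 s of the nadir, or abrupt onset (a fall
#'   of >= 15 bpm within the first 30 s): `variable_decel`;
#' * |lag| <= 15 s: `early_decel`;
#' * 15 < lag <= 60 s (nadir after the peak): `late_decel`;
#' * anything else (e.g. nadir well before the peak): `variable_decel`.
#'
#' @param fhr complete FHR vector.
#' @param baseline baseline bpm.
#' @param uc_smooth smoothed UC vector (same length).
#' @param fs sample rate (Hz).
#' @return event data.frame as in [detect_accelerations()].
#' @export
detect_decelerations <- function(fhr, baseline, uc_smooth, fs = 4) {
  runs <- true_runs(fhr <= baseline - 15)
  runs <- runs[runs$length >= 15 * fs, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty_events())
  peaks_s <- uc_peaks(uc_smooth, fs)
  ev <- lapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]; e <- runs$end[i]
    seg <- fhr[s:e]
    nadir_rel <- which.min(seg)
    nadir_s <- (s + nadir_rel - 2) / fs
    dur_s <- (e - s + 1) / fs
    lag <- NA_real_
    if (length(peaks_s)) {
      nearest <- peaks_s[which.min(abs(peaks_s - nadir_s))]
      lag <- nadir_s - nearest
    }
    # abrupt onset: falls >= 15 bpm below baseline within 30 s of onset
    onset_win <- seg[seq_len(min(length(seg), 30 * fs))]
    abrupt <- (baseline - min(onset_win)) >= 15 &&
      which.min(onset_win) <= 30 * fs
    kind <-
      if (dur_s >= 120) "prolonged_decel"
      else if (is.na(lag) || abs(lag) > 60) "variable_decel"
      else if (abs(lag) <= 15) "early_decel"
      else if (lag > 15 && lag <= 60) "late_decel"
      else "variable_decel"
    if (kind == "early_decel" && abrupt && abs(lag) > 5) kind <- "variable_decel"
    data.frame(kind = kind, onset_s = (s - 1) / fs, end_s = e / fs,
               extremum_bpm = min(seg), lag_vs_uc_peak_s = lag)
  })
  do.call(rbind, ev)
}

empty_events <- function() {
  data.frame(kind = character(), onset_s = numeric(), end_s = numeric(),
             extremum_bpm = numeric(), lag_vs_uc_peak_s = numeric())
}

# Contraction peaks of the smoothed UC signal: local maxima separated by at
# least 60 s, with amplitude above the midpoint of the channel's range
# (a flat channel has no contractions). Returns peak times in seconds.
uc_peaks <- function(uc, fs = 4) {
  n <- length(uc)
  if (n < 3L || diff(range(uc)) < 1e-8) return(numeric())
  thr <- min(uc) + 0.4 * diff(range(uc))
  d <- diff(uc)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[uc[cand] >= thr]
  if (!length(cand)) return(numeric())
  # enforce 60 s separation, keeping the taller peak
  keep <- integer()
  for (i in cand) {
    if (length(keep) && (i - keep[length(keep)]) < 60 * fs) {
      if (uc[i] > uc[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  (keep - 1) / fs
}

#' Per-minute variability
#'
#' Long-term variability per non-overlapping 1-minute window is the
#' max - min of FHR over the window, excluding samples inside detected
#' accelerations/decelerations; the aggregate is the median of window
#' amplitudes.  Short-term variability per window is the mean absolute
#' successive difference.  Windows fully covered by events yield `NA` and
#' are dropped from aggregates.
#'
#' @param fhr complete FHR vector.
#' @param events event data.frame from the detectors (may be empty).
#' @param fs sample rate (Hz).
#' @return list with `ltv_per_min`, `stv_per_min` (vectors, one per full
#'   window) and `ltv` (median aggregate, bpm).
#' @export
compute_variability <- function(fhr, events = empty_events(), fs = 4) {
  n <- length(fhr)
  in_event <- rep(FALSE, n)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      s <- floor(events$onset_s[i] * fs) + 1L
      e <- min(n, ceiling(events$end_s[i] * fs))
      in_event[s:e] <- TRUE
    }
  }
  wlen <- 60L * fs
  nwin <- n %/% wlen
  ltv <- stv <- rep(NA_real_, nwin)
  for (w in seq_len(nwin)) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    ok <- idx[!in_event[idx]]
    if (length(ok) >= 2L) {
      x <- fhr[ok]
      ltv[w] <- max(x) - min(x)
      stv[w] <- mean(abs(diff(x)))
    }
  }
  list(ltv_per_min = ltv, stv_per_min = stv,
       ltv = stats::median(ltv, na.rm = TRUE))
}

#' Names and order of the 44-feature vector
#'
#' The roster spans the guideline categories a clinical reader scores —
#' baseline, variability, accelerations, decelerations (typed early / late
#' / variable / prolonged) — plus uterine-activity context.  It lives in a
#' manifest file (`inst/extdata/feature_manifest.csv`) so it can be revised
#' without touching code; this accessor reads it.
#'
#' @return character vector of 44 feature names, in canonical order.
#' @export
feature_names <- function() {
  path <- system.file("extdata", "feature_manifest.csv", package = "ctgdx")
  utils::read.csv(path)$name
}

#' Build the 44-element feature vector
#'
#' Deterministic descriptor of a cleaned segment, in the fixed order given
#' by [feature_names()].  Durations are seconds; fractions are of segment
#' samples; counts of absent event types are 0 and their duration/depth/lag
#' summaries are 0 (not `NA`) so the vector is always complete.
#' Bradycardia/tachycardia fractions use the conventional 110/160 bpm
#' limits.
#'
#' @param clean_trace a `ctg_clean_trace` from [clean()], or a bare
#'   [ctg_trace()] assumed already clean.
#' @return named numeric vector of length 44, plus attribute `events`
#'   (the detected event table).
#' @export
build_feature_vector <- function(clean_trace) {
  tr <- if (inherits(clean_trace, "ctg_clean_trace")) clean_trace$trace
        else clean_trace
  stopifnot(inherits(tr, "ctg_trace"))
  fhr <- tr$fhr; uc <- tr$uc; fs <- tr$sample_rate
  if (anyNA(fhr))
    stop_ctg("feature extraction requires a cleaned (complete) segment",
             "ctgdx_invalid_trace")
  n <- length(fhr)
  mins <- n / fs / 60

  baseline <- estimate_baseline(fhr)
  acc <- detect_accelerations(fhr, baseline, fs)
  dec <- detect_decelerations(fhr, baseline, uc, fs)
  events <- rbind(acc, dec)
  v <- compute_variability(fhr, events, fs)
  peaks <- uc_peaks(uc, fs)

  t <- trace_times(tr)
  drift <- if (n > 1) stats::coef(stats::lm.fit(cbind(1, t / 60), fhr))[2] else 0

  typed <- function(kind) dec[dec$kind == kind, , drop = FALSE]
  type_feats <- function(kind) {
    d <- typed(kind)
    lag <- d$lag_vs_uc_peak_s[!is.na(d$lag_vs_uc_peak_s)]
    c(count = nrow(d),
      total_duration_s = sum(d$end_s - d$onset_s),
      mean_depth_bpm = if (nrow(d)) mean(baseline - d$extremum_bpm) else 0,
      mean_lag_s = if (length(lag)) mean(lag) else 0)
  }

  agg0 <- function(x, f) if (length(x) && any(!is.na(x))) f(x, na.rm = TRUE) else 0
  dec_dur <- sum(dec$end_s - dec$onset_s)
  out <- c(
    baseline_bpm = baseline,
    baseline_drift_bpm_per_min = unname(drift),
    bradycardia_fraction = mean(fhr < 110),
    tachycardia_fraction = mean(fhr > 160),
    stv_mean_bpm = agg0(v$stv_per_min, mean),
    stv_median_bpm = agg0(v$stv_per_min, stats::median),
    stv_min_bpm = agg0(v$stv_per_min, min),
    stv_max_bpm = agg0(v$stv_per_min, max),
    stv_low_fraction = agg0(v$stv_per_min < 1, mean),
    ltv_mean_bpm = agg0(v$ltv_per_min, mean),
    ltv_median_bpm = agg0(v$ltv_per_min, stats::median),
    ltv_min_bpm = agg0(v$ltv_per_min, min),
    ltv_max_bpm = agg0(v$ltv_per_min, max),
    ltv_reduced_fraction = agg0(v$ltv_per_min < 5, mean),
    ltv_marked_fraction = agg0(v$ltv_per_min > 25, mean),
    accel_count = nrow(acc),
    accel_total_duration_s = sum(acc$end_s - acc$onset_s),
    accel_mean_duration_s = if (nrow(acc)) mean(acc$end_s - acc$onset_s) else 0,
    accel_mean_amplitude_bpm = if (nrow(acc)) mean(acc$extremum_bpm - baseline) else 0,
    accel_max_amplitude_bpm = if (nrow(acc)) max(acc$extremum_bpm - baseline) else 0)
  for (kind in c("early_decel", "late_decel", "variable_decel", "prolonged_decel")) {
    tf <- type_feats(kind)
    names(tf) <- paste(kind, names(tf), sep = "_")
    out <- c(out, tf)
  }
  out <- c(out,
    decel_count_total = nrow(dec),
    decel_total_duration_s = dec_dur,
    decel_max_depth_bpm = if (nrow(dec)) max(baseline - dec$extremum_bpm) else 0,
    decel_time_fraction = dec_dur / (n / fs),
    uc_contraction_count = length(peaks),
    uc_mean_interval_s = if (length(peaks) > 1) mean(diff(peaks)) else 0,
    uc_mean_amplitude = if (length(peaks)) mean(uc[round(peaks * fs) + 1]) - min(uc) else 0,
    decel_per_contraction_ratio = if (length(peaks)) nrow(dec) / length(peaks) else 0)

  stopifnot(identical(names(out), feature_names()))
  attr(out, "events") <- events
  out
}
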