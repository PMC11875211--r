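#' Trace-generator parameters
#'
#' Describes one synthetic intrapartum recording: a baseline FHR level, a
#' band-limited variability process, acceleration bumps, deceleration dips
#' time-locked to contraction peaks at a configurable lag (positive lag =
#' nadir after the peak, i.e. late), and a regular contraction train.
#' Event counts are deterministic (`round(rate x duration)`) so the
#' returned ground-truth ledger is exactly verifiable; placement is random.
#'
#' @param baseline_bpm baseline FHR level, bpm (must lie in (50, 200)).
#' @param variability_amplitude_bpm typical per-minute peak-to-peak
#'   amplitude of the variability process, bpm; 0 gives a noiseless trace.
#' @param accel_rate_per_h,decel_rate_per_h event rates per hour.
#' @param decel_lag_s nadir minus UC-peak lag, seconds (> 0 = late).
#' @param accel_amplitude_bpm,accel_duration_s acceleration bump shape.
#' @param decel_depth_bpm,decel_duration_s deceleration dip shape.
#' @param contraction_period_s spacing of contraction peaks, seconds.
#' @param duration_s trace length, seconds; >= 3000 so the 50-minute
#'   pre-delivery span is covered.
#' @return list of class `trace_gen_params`.
#' @export
trace_gen_params <- function(baseline_bpm = 140,
                             variability_amplitude_bpm = 10,
                             accel_rate_per_h = 4,
                             decel_rate_per_h = 0,
                             decel_lag_s = 0,
                             accel_amplitude_bpm = 25,
                             accel_duration_s = 60,
                             decel_depth_bpm = 30,
                             decel_duration_s = 60,
                             contraction_period_s = 180,
                             duration_s = 3600) {
  if (baseline_bpm <= 50 || baseline_bpm >= 200)
    stop_ctg("baseline must lie strictly inside (50, 200) bpm",
             "ctgdx_invalid_params")
  if (accel_rate_per_h < 0 || decel_rate_per_h < 0 ||
      variability_amplitude_bpm < 0)
    stop_ctg("rates and amplitudes must be non-negative", "ctgdx_invalid_params")
  if (duration_s < 3000)
    stop_ctg("duration too short: need >= 3000 s to cover the pre-delivery span",
             "ctgdx_invalid_params")
  structure(as.list(environment()), class = "trace_gen_params")
}

# Raised-cosine (Hann) bump of given peak amplitude over [0, dur].
hann_bump <- function(t_rel, dur, amp) amp * sin(pi * t_rel / dur)^2

#' Generate a clean synthetic CTG trace
#'
#' FHR = baseline + smoothed-noise variability + Hann acceleration bumps +
#' Hann deceleration dips whose nadirs sit `decel_lag_s` seconds after the
#' nearest contraction peak; UC = tonus + Gaussian bells at
#' `contraction_period_s`.  Delivery time is set to `duration_s` (the trace
#' ends at delivery).
#'
#' @param params a [trace_gen_params()].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param case_id case identifier.
#' @return a [ctg_trace()] with attribute `events`: the ground-truth ledger
#'   (`kind, onset_s, end_s, extremum_bpm, lag_vs_uc_peak_s`).
#' @export
generate_clean_trace <- function(params = trace_gen_params(), seed = NULL,
                                 case_id = "sim") {
  stopifnot(inherits(params, "trace_gen_params"))
  with_seed(seed, {
    fs <- 4
    n <- as.integer(params$duration_s * fs)
    t <- (seq_len(n) - 1) / fs

    # contraction train: Gaussian bells on a resting tonus
    period <- params$contraction_period_s
    peaks <- seq(period / 2, params$duration_s - period / 2, by = period)
    uc <- rep(10, n)
    for (p in peaks) uc <- uc + 40 * exp(-0.5 * ((t - p) / (period / 8))^2)

    fhr <- rep(params$baseline_bpm, n)
    if (params$variability_amplitude_bpm > 0) {
      z <- centered_ma(stats::rnorm(n), 6)
      z <- z / stats::sd(z)
      fhr <- fhr + z * params$variability_amplitude_bpm / 4
    }

    dur_h <- params$duration_s / 3600
    n_acc <- round(params$accel_rate_per_h * dur_h)
    n_dec <- round(params$decel_rate_per_h * dur_h)

    events <- empty_events()
    occupied <- logical(n)
    reserve <- function(s_idx, e_idx, margin) {
      lo <- max(1L, s_idx - margin); hi <- min(n, e_idx + margin)
      if (any(occupied[lo:hi])) return(FALSE)
      occupied[lo:hi] <<- TRUE
      TRUE
    }

    # decelerations first: they are tied to contraction peaks
    if (n_dec > 0) {
      dur <- params$decel_duration_s
      ok_peaks <- peaks[peaks + params$decel_lag_s - dur / 2 > 0 &
                        peaks + params$decel_lag_s + dur / 2 < params$duration_s]
      if (length(ok_peaks) < n_dec)
        stop_ctg("not enough contractions to host the requested decelerations",
                 "ctgdx_invalid_params")
      sel <- sort(ok_peaks[sample.int(length(ok_peaks), n_dec)])
      for (p in sel) {
        nadir <- p + params$decel_lag_s
        onset <- nadir - dur / 2
        s_idx <- floor(onset * fs) + 1L; e_idx <- min(n, ceiling((onset + dur) * fs))
        reserve(s_idx, e_idx, 30L * fs)
        rel <- t - onset
        in_ev <- rel >= 0 & rel <= dur
        fhr[in_ev] <- fhr[in_ev] - hann_bump(rel[in_ev], dur, params$decel_depth_bpm)
        events <- rbind(events, data.frame(
          kind = "deceleration", onset_s = onset, end_s = onset + dur,
          extremum_bpm = params$baseline_bpm - params$decel_depth_bpm,
          lag_vs_uc_peak_s = params$decel_lag_s))
      }
    }

    if (n_acc > 0) {
      dur <- params$accel_duration_s
      placed <- 0L; tries <- 0L
      while (placed < n_acc && tries < 1000L) {
        tries <- tries + 1L
        onset <- stats::runif(1, 30, params$duration_s - dur - 30)
        s_idx <- floor(onset * fs) + 1L; e_idx <- ceiling((onset + dur) * fs)
        if (!reserve(s_idx, e_idx, 30L * fs)) next
        rel <- t - onset
        in_ev <- rel >= 0 & rel <= dur
        fhr[in_ev] <- fhr[in_ev] + hann_bump(rel[in_ev], dur, params$accel_amplitude_bpm)
        events <- rbind(events, data.frame(
          kind = "acceleration", onset_s = onset, end_s = onset + dur,
          extremum_bpm = params$baseline_bpm + params$accel_amplitude_bpm,
          lag_vs_uc_peak_s = NA_real_))
        placed <- placed + 1L
      }
      if (placed < n_acc)
        stop_ctg("could not place all requested accelerations without overlap",
                 "ctgdx_invalid_params")
    }

    out <- ctg_trace(fhr, uc, delivery_time = params$duration_s,
                     case_id = case_id)
    attr(out, "events") <- events[order(events$onset_s), , drop = FALSE]
    out
  })
}

#' Artifact-injection parameters
#'
#' The artifact classes the cleaner removes, inverted: signal-dropout zero
#' runs, out-of-range spike samples (>= 200 or <= 50 bpm), and in-range
#' jump samples deviating by more than 25 bpm from the local level.
#'
#' @param dropout_rate_per_h zero-run events per hour.
#' @param dropout_len_s length-2 bounds (s) for short dropout runs.
#' @param spike_rate_per_h single-sample spike/jump events per hour.
#' @param spike_magnitude_bpm length-2 bounds (bpm) for jump deviations.
#'   The lower bound must clear the 25 bpm removal rule by more than the
#'   variability noise floor (~4-5 bpm at default amplitudes), otherwise an
#'   injected jump can be physically indistinguishable from variability and
#'   is not removable; the default floor of 35 guarantees removability.
#' @param long_dropout_prob probability that a dropout is >= 15 s long
#'   (which discontinues the recording at cleaning time).
#' @return list of class `artifact_params`.
#' @export
artifact_params <- function(dropout_rate_per_h = 6,
                            dropout_len_s = c(1, 8),
                            spike_rate_per_h = 12,
                            spike_magnitude_bpm = c(35, 60),
                            long_dropout_prob = 0) {
  stopifnot(dropout_rate_per_h >= 0, spike_rate_per_h >= 0,
            long_dropout_prob >= 0, long_dropout_prob <= 1,
            length(dropout_len_s) == 2, length(spike_magnitude_bpm) == 2)
  structure(as.list(environment()), class = "artifact_params")
}

#' Inject artifacts into a clean trace
#'
#' Zero rates leave the trace untouched.  The returned ledger records every
#' corrupted sample index and its artifact type, so cleaning round trips
#' can be verified exactly.
#'
#' @param trace a clean [ctg_trace()].
#' @param params an [artifact_params()].
#' @param seed integer seed or `NULL`.
#' @return the corrupted [ctg_trace()] with attribute `artifact_ledger`:
#'   data.frame(`index`, `type`), type in
#'   `{dropout, long_dropout, spike_high, spike_low, jump}`.
#' @export
corrupt_trace <- function(trace, params = artifact_params(), seed = NULL) {
  stopifnot(inherits(trace, "ctg_trace"), inherits(params, "artifact_params"))
  with_seed(seed, {
    fs <- trace$sample_rate
    n <- length(trace$fhr)
    fhr <- trace$fhr
    dur_h <- n / fs / 3600
    ledger <- data.frame(index = integer(), type = character())
    taken <- logical(n)

    n_drop <- round(params$dropout_rate_per_h * dur_h)
    for (i in seq_len(n_drop)) {
      long <- stats::runif(1) < params$long_dropout_prob
      len_s <- if (long) stats::runif(1, 15, 30)
               else stats::runif(1, params$dropout_len_s[1], params$dropout_len_s[2])
      len <- max(1L, round(len_s * fs))
      for (try in 1:100) {
        s <- sample.int(n - len + 1L, 1)
        idx <- s:(s + len - 1L)
        if (!any(taken[idx])) { taken[idx] <- TRUE; break } else idx <- NULL
      }
      if (is.null(idx)) next
      fhr[idx] <- 0
      ledger <- rbind(ledger, data.frame(
        index = idx, type = if (long) "long_dropout" else "dropout"))
    }

    n_spk <- round(params$spike_rate_per_h * dur_h)
    free <- which(!taken)
    n_spk <- min(n_spk, length(free))
    if (n_spk > 0) {
      at <- free[sample.int(length(free), n_spk)]
      for (i in at) {
        kind <- sample(c("spike_high", "spike_low", "jump"), 1)
        fhr[i] <- switch(kind,
          spike_high = stats::runif(1, 200, 240),
          spike_low = stats::runif(1, 10, 50),
          jump = fhr[i] + sample(c(-1, 1), 1) *
            stats::runif(1, params$spike_magnitude_bpm[1],
                         params$spike_magnitude_bpm[2]))
        ledger <- rbind(ledger, data.frame(index = i, type = kind))
      }
    }
    out <- ctg_trace(fhr, trace$uc, trace$delivery_time, trace$case_id, fs)
    attr(out, "artifact_ledger") <- ledger[order(ledger$index), , drop = FALSE]
    attr(out, "events") <- attr(trace, "events")
    out
  })
}

#' Outcome-model parameters
#'
#' Logistic model for the (unobserved) asphyxia mechanism: the linear
#' predictor is `intercept + beta . (late-deceleration count, variability
#' deficit, bradycardia fraction)` on ground-truth trace features.
#'
#' @param intercept logistic intercept; `NULL` means calibrate at sampling
#'   time so the mean probability equals `target_prevalence`.
#' @param beta named numeric coefficients for `late_decel_count`,
#'   `variability_deficit`, `bradycardia_fraction`.
#' @param target_prevalence cohort positive fraction, in (0, 1);
#'   default 31/489 (the evaluated-cohort rate).
#' @return list of class `outcome_model_params`.
#' @export
outcome_model_params <- function(intercept = NULL,
                                 beta = c(late_decel_count = 0.9,
                                          variability_deficit = 2.0,
                                          bradycardia_fraction = 5.0),
                                 target_prevalence = 31 / 489) {
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop_ctg("target_prevalence must lie in (0, 1)", "ctgdx_invalid_params")
  structure(list(intercept = intercept, beta = beta,
                 target_prevalence = target_prevalence),
            class = "outcome_model_params")
}

outcome_linpred <- function(features, params) {
  features <- as.data.frame(features)
  lp <- rep(0, nrow(features))
  for (nm in names(params$beta))
    lp <- lp + params$beta[[nm]] * (features[[nm]] %||% 0)
  lp
}

calibrate_intercept <- function(lp, prevalence) {
  stats::uniroot(function(a) mean(stats::plogis(a + lp)) - prevalence,
                 c(-30, 30))$root
}

# Label-conditional Apgar/pH draws, consistent with the labeling rule by
# construction (positives satisfy at least one criterion; negatives none).
draw_outcome_fields <- function(label) {
  n <- length(label)
  apgar1 <- integer(n); apgar5 <- integer(n); ph <- numeric(n)
  neg <- !label
  apgar1[neg] <- sample(6:10, sum(neg), replace = TRUE,
                        prob = c(0.05, 0.1, 0.3, 0.4, 0.15))
  apgar5[neg] <- pmin(10L, apgar1[neg] + sample(0:2, sum(neg), TRUE))
  ph[neg] <- round(stats::runif(sum(neg), 7.12, 7.42), 2)
  if (any(label)) {
    np <- sum(label)
    acidotic <- stats::runif(np) < 0.6
    ph[label] <- ifelse(acidotic, round(stats::runif(np, 6.85, 7.09), 2),
                        round(stats::runif(np, 7.12, 7.35), 2))
    low1 <- stats::runif(np) < 0.8 | !acidotic  # guarantee a firing criterion
    apgar1[label] <- ifelse(low1, sample(1:5, np, TRUE), sample(6:9, np, TRUE))
    apgar5[label] <- ifelse(low1, pmin(10L, apgar1[label] + sample(0:4, np, TRUE)),
                            sample(6:10, np, TRUE))
  }
  data.frame(apgar_1min = apgar1, apgar_5min = apgar5, ua_ph = ph)
}

#' Sample neonatal outcomes from ground-truth features
#'
#' Draws a Bernoulli asphyxia label per case with probability
#' `plogis(intercept + beta . features)`, then draws Apgar scores and
#' umbilical-artery pH from label-conditional distributions chosen so that
#' [label_outcome()] reproduces the drawn label by construction.
#'
#' @param features data.frame (one row per case) with columns
#'   `late_decel_count`, `variability_deficit`, `bradycardia_fraction`
#'   (missing columns contribute 0).
#' @param params an [outcome_model_params()].
#' @param seed integer seed or `NULL`.
#' @return data.frame with `apgar_1min`, `apgar_5min`, `ua_ph`, `label`.
#' @export
sample_outcome <- function(features, params = outcome_model_params(),
                           seed = NULL) {
  with_seed(seed, {
    lp <- outcome_linpred(features, params)
    a <- params$intercept %||% calibrate_intercept(lp, params$target_prevalence)
    p <- stats::plogis(a + lp)
    label <- stats::runif(length(p)) < p
    cbind(draw_outcome_fields(label), label = label)
  })
}

#' Rater-panel parameters
#'
#' @param sensitivity,specificity per-judgment operating point of a rater,
#'   in `[0, 1]`; defaults are the observed pooled human operating point
#'   (22.58 % / 91.92 %).
#' @param n_raters panel size (the study solicited 34 obstetricians and
#'   22 midwives).
#' @param figures_per_rater cases shown to each rater (default 50).
#' @param positives_per_rater positive cases among them (default 10).
#' @param obstetrician_fraction fraction of the panel labelled
#'   `obstetrician` (rest `midwife`).
#' @param response_dropout probability a solicited response is never
#'   returned (models attrition; default 0).
#' @return list of class `rater_model_params`.
#' @export
rater_model_params <- function(sensitivity = 0.2258, specificity = 0.9192,
                               n_raters = 56, figures_per_rater = 50,
                               positives_per_rater = 10,
                               obstetrician_fraction = 34 / 56,
                               response_dropout = 0) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            positives_per_rater <= figures_per_rater,
            response_dropout >= 0, response_dropout <= 1)
  structure(as.list(environment()), class = "rater_model_params")
}

#' Simulate a rater panel
#'
#' Each rater is assigned `figures_per_rater` cases sampled without
#' replacement — `positives_per_rater` positives and the balance negatives
#' — and judges each independently: positives are called positive with
#' probability `sensitivity`, negatives are called negative with
#' probability `specificity`.
#'
#' @param truth_labels logical vector of cohort truth labels; names (or
#'   indices) become `case_id`s.
#' @param params a [rater_model_params()].
#' @param seed integer seed or `NULL`.
#' @return long data.frame `case_id, rater_id, rater_class, judgment`
#'   (judgment 1 = positive).
#' @export
simulate_raters <- function(truth_labels, params = rater_model_params(),
                            seed = NULL) {
  stopifnot(inherits(params, "rater_model_params"))
  ids <- names(truth_labels) %||% as.character(seq_along(truth_labels))
  pos_ids <- ids[truth_labels]
  neg_ids <- ids[!truth_labels]
  n_neg_quota <- params$figures_per_rater - params$positives_per_rater
  if (length(pos_ids) < params$positives_per_rater ||
      length(neg_ids) < n_neg_quota)
    stop_ctg(sprintf(
      "not enough cases for the per-rater quota: have %d positive / %d negative, need %d / %d",
      length(pos_ids), length(neg_ids), params$positives_per_rater, n_neg_quota),
      "ctgdx_invalid_params")
  with_seed(seed, {
    n_obs <- round(params$n_raters * params$obstetrician_fraction)
    out <- vector("list", params$n_raters)
    for (r in seq_len(params$n_raters)) {
      shown_pos <- sample(pos_ids, params$positives_per_rater)
      shown_neg <- sample(neg_ids, n_neg_quota)
      truth <- c(rep(TRUE, length(shown_pos)), rep(FALSE, length(shown_neg)))
      call_pos <- ifelse(truth,
                         stats::runif(length(truth)) < params$sensitivity,
                         stats::runif(length(truth)) >= params$specificity)
      out[[r]] <- data.frame(
        case_id = c(shown_pos, shown_neg),
        rater_id = sprintf("r%03d", r),
        rater_class = if (r <= n_obs) "obstetrician" else "midwife",
        judgment = as.integer(call_pos))
    }
    res <- do.call(rbind, out)
    if (params$response_dropout > 0)
      res <- res[stats::runif(nrow(res)) >= params$response_dropout, , drop = FALSE]
    rownames(res) <- NULL
    res
  })
}

#' Generate a full synthetic study cohort
#'
#' Emits everything downstream stages consume: per-case ground-truth risk
#' features, outcome records with exactly `n_pos` positive labels (the
#' labels are drawn without replacement with probability proportional to
#' each case's logistic risk, so risk features and outcome correlate),
#' a rater panel, two model-score channels (a probability-like score in
#' `[0, 1]` and a binary call) at configurable operating points, and —
#' optionally — the synthetic traces themselves.
#'
#' @param n cohort size (default 489, the evaluated-cohort size).
#' @param n_pos number of positive outcomes (default 31).
#' @param seed integer seed or `NULL`.
#' @param rater_params a [rater_model_params()]; `n_raters = NULL` in the
#'   default sizes the panel to ~4 views per figure.
#' @param outcome_params an [outcome_model_params()].
#' @param dl_operating c(sensitivity, specificity) of the score channel at
#'   cutoff 0.5 (defaults: the DL observed point 22.58 % / 81.88 %).
#' @param ml_operating c(sensitivity, specificity) of the binary channel
#'   (defaults: the ML observed point 3.23 % / 93.89 %).
#' @param traces if `TRUE`, also generate one clean [ctg_trace()] per case
#'   reflecting its risk features (slower; default `FALSE`).
#' @param trace_duration_s duration of generated traces.
#' @return list with `cases` (data.frame: case_id, truth, apgar_1min,
#'   apgar_5min, ua_ph, dl_score, ml_call), `features` (ground-truth risk
#'   features), `ratings` (long rater table), and `traces` (list or `NULL`).
#' @export
generate_study_cohort <- function(n = 489, n_pos = 31, seed = NULL,
                                  rater_params = NULL,
                                  outcome_params = outcome_model_params(),
                                  dl_operating = c(0.2258, 0.8188),
                                  ml_operating = c(0.0323, 0.9389),
                                  traces = FALSE,
                                  trace_duration_s = 3600) {
  stopifnot(n >= 1, n_pos >= 0, n_pos <= n)
  with_seed(seed, {
    ids <- sprintf("c%04d", seq_len(n))

    feats <- data.frame(
      case_id = ids,
      late_decel_count = stats::rpois(n, 1.0),
      variability_amplitude = stats::runif(n, 5, 20),
      bradycardia_fraction = stats::rbeta(n, 1, 30))
    feats$variability_deficit <- pmax(0, 10 - feats$variability_amplitude) / 10

    # exactly n_pos positives, weighted by logistic risk
    lp <- outcome_linpred(feats, outcome_params)
    a <- outcome_params$intercept %||%
      calibrate_intercept(lp, max(1, n_pos) / n)
    p <- stats::plogis(a + lp)
    label <- rep(FALSE, n)
    if (n_pos > 0) label[sample.int(n, n_pos, prob = p)] <- TRUE

    outc <- draw_outcome_fields(label)

    # score channel: pick the binary call at the configured operating point,
    # then draw the score on the matching side of the 0.5 cutoff
    call_pos_dl <- ifelse(label, stats::runif(n) < dl_operating[1],
                          stats::runif(n) >= dl_operating[2])
    dl_score <- ifelse(call_pos_dl, stats::runif(n, 0.5, 1),
                       stats::runif(n, 0, 0.5))
    ml_call <- as.integer(ifelse(label, stats::runif(n) < ml_operating[1],
                                 stats::runif(n) >= ml_operating[2]))

    if (is.null(rater_params)) {
      # ~4 views per figure; quotas clamped so small desk-scale cohorts work
      npos_q <- min(10L, n_pos)
      nneg_q <- min(40L, n - n_pos)
      rp <- rater_model_params(n_raters = max(1L, ceiling(4 * n / 50)),
                               figures_per_rater = npos_q + nneg_q,
                               positives_per_rater = npos_q)
    } else rp <- rater_params
    names(label) <- ids
    ratings <- simulate_raters(label, rp, seed = NULL)

    trace_list <- NULL
    if (traces) {
      trace_list <- lapply(seq_len(n), function(i) {
        tp <- trace_gen_params(
          baseline_bpm = min(170, max(115, stats::rnorm(1, 140, 8))),
          variability_amplitude_bpm = feats$variability_amplitude[i],
          accel_rate_per_h = stats::rpois(1, 3),
          decel_rate_per_h = feats$late_decel_count[i] / (trace_duration_s / 3600),
          decel_lag_s = 30,
          duration_s = trace_duration_s)
        generate_clean_trace(tp, seed = NULL, case_id = ids[i])
      })
      names(trace_list) <- ids
    }

    list(cases = data.frame(case_id = ids, truth = label, outc,
                            dl_score = dl_score, ml_call = ml_call,
                            row.names = NULL),
         features = feats, ratings = ratings, traces = trace_list)
  })
}
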