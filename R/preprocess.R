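#' Cleaning parameters
#'
#' Defaults encode the published cleaning rules for this device class:
#' recording is discontinued at the first zero run of >= 15 s; any other 0,
#' any FHR >= 200 bpm or <= 50 bpm is removed; any sample deviating by
#' more than 25 bpm from the mean of its 15 s window is removed; removed
#' values are filled by linear interpolation; UC is smoothed with a 60 s
#' moving average; the analysis segment is the 30 minutes ending 20 minutes
#' before delivery.
#'
#' @param zero_run_discontinue_s zero-run length (s) that discontinues the
#'   recording (inclusive: exactly 15.0 s triggers).
#' @param fhr_max_bpm upper validity bound; values `>=` this are removed.
#' @param fhr_min_bpm lower validity bound; values `<=` this are removed.
#' @param spike_window_s window (s) for the deviation-from-local-mean rule.
#' @param spike_max_dev_bpm maximum allowed absolute deviation (bpm);
#'   strictly greater deviations are removed, exactly 25 is kept.
#' @param uc_smooth_window_s UC moving-average window (s).
#' @param segment_len_s analysis-segment length (s).
#' @param segment_end_offset_s gap (s) between segment end and delivery.
#' @param truncate_at_zero_run if `FALSE`, qualifying zero runs are masked
#'   instead of discontinuing the recording (sensitivity switch; the
#'   published rule is `TRUE`).
#' @return a list of class `cleaning_params`.
#' @export
cleaning_params <- function(zero_run_discontinue_s = 15,
                            fhr_max_bpm = 200,
                            fhr_min_bpm = 50,
                            spike_window_s = 15,
                            spike_max_dev_bpm = 25,
                            uc_smooth_window_s = 60,
                            segment_len_s = 1800,
                            segment_end_offset_s = 1200,
                            truncate_at_zero_run = TRUE) {
  p <- list(zero_run_discontinue_s = zero_run_discontinue_s,
            fhr_max_bpm = fhr_max_bpm, fhr_min_bpm = fhr_min_bpm,
            spike_window_s = spike_window_s,
            spike_max_dev_bpm = spike_max_dev_bpm,
            uc_smooth_window_s = uc_smooth_window_s,
            segment_len_s = segment_len_s,
            segment_end_offset_s = segment_end_offset_s,
            truncate_at_zero_run = isTRUE(truncate_at_zero_run))
  num <- unlist(p[1:8])
  if (any(!is.finite(num)) || any(num <= 0))
    stop_ctg("all cleaning parameters must be positive", "ctgdx_invalid_params")
  class(p) <- "cleaning_params"
  p
}

#' Discontinue a recording at a long zero run
#'
#' If any run of consecutive exact-zero FHR samples lasts at least
#' `zero_run_discontinue_s` (15 s = 60 samples at 4 Hz), the trace is cut
#' immediately before the first sample of the first such run; shorter zero
#' runs are left for masking.
#'
#' @param trace a raw [ctg_trace()].
#' @param params a [cleaning_params()].
#' @return the (possibly shortened) trace, with attribute
#'   `truncation_point` (1-based index where the qualifying run began, or
#'   `NA` if no truncation).
#' @export
truncate_at_zero_run <- function(trace, params = cleaning_params()) {
  stopifnot(inherits(trace, "ctg_trace"))
  min_run <- params$zero_run_discontinue_s * trace$sample_rate
  runs <- true_runs(!is.na(trace$fhr) & trace$fhr == 0)
  hit <- runs[runs$length >= min_run, , drop = FALSE]
  if (!params$truncate_at_zero_run || nrow(hit) == 0L) {
    attr(trace, "truncation_point") <- NA_integer_
    return(trace)
  }
  cut <- hit$start[1]
  if (cut <= 1L)
    stop_ctg("unusable trace: recording discontinued at its first sample",
             "ctgdx_unusable_trace")
  out <- ctg_trace(trace$fhr[seq_len(cut - 1L)], trace$uc[seq_len(cut - 1L)],
                   trace$delivery_time, trace$case_id, trace$sample_rate)
  attr(out, "truncation_point") <- cut
  out
}

#' Mask physiologically invalid FHR samples
#'
#' Removes (sets to `NA`) every remaining exact 0, every value at or above
#' `fhr_max_bpm` and every value at or below `fhr_min_bpm`.  Boundary
#' semantics are inclusive on both validity bounds: 200 and 50 are removed,
#' 199 and 51 are kept.
#'
#' @param fhr numeric FHR vector (bpm).
#' @param params a [cleaning_params()].
#' @return the masked vector, with attribute `removal_counts`
#'   (named: zero, high, low).
#' @export
mask_invalid <- function(fhr, params = cleaning_params()) {
  obs <- !is.na(fhr)
  zero <- obs & fhr == 0
  high <- obs & !zero & fhr >= params$fhr_max_bpm
  low <- obs & !zero & fhr <= params$fhr_min_bpm
  fhr[zero | high | low] <- NA_real_
  attr(fhr, "removal_counts") <-
    c(zero = sum(zero), high = sum(high), low = sum(low))
  fhr
}

#' Mask spike artifacts by deviation from the local-window mean
#'
#' A sample is removed when its absolute deviation from the mean of its
#' centered 15 s window strictly exceeds 25 bpm.  The window mean includes
#' the sample itself and excludes already-masked samples; decisions are made
#' in a single pass against the pre-pass values (masking one spike does not
#' change its neighbours' window means).
#'
#' @param fhr numeric FHR vector with range-invalid samples already `NA`.
#' @param params a [cleaning_params()].
#' @return the masked vector, with attribute `removal_counts` (named: spike).
#' @export
mask_spikes <- function(fhr, params = cleaning_params()) {
  n <- length(fhr)
  half <- as.integer(params$spike_window_s * 4 / 2)  # 30 samples => 61-sample window spans 15 s
  obs <- !is.na(fhr)
  vals <- ifelse(obs, fhr, 0)
  cs <- cumsum(c(0, vals))
  cn <- cumsum(c(0, obs))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- cn[hi + 1L] - cn[lo]
  mu <- ifelse(cnt > 0, (cs[hi + 1L] - cs[lo]) / cnt, NA_real_)
  spike <- obs & cnt > 0 & abs(fhr - mu) > params$spike_max_dev_bpm
  fhr[spike] <- NA_real_
  attr(fhr, "removal_counts") <- c(spike = sum(spike))
  fhr
}

#' Fill masked samples by linear interpolation
#'
#' Interior gaps are filled linearly between the nearest observed
#' neighbours; leading/trailing gaps take the nearest observed value (a
#' line needs two anchors).
#'
#' @param fhr numeric vector with `NA` gaps and at least one observed value.
#' @return a complete numeric vector of the same length.
#' @export
interpolate_gaps <- function(fhr) {
  obs <- which(!is.na(fhr))
  if (length(obs) == 0L)
    stop_ctg("unusable trace: no observed FHR samples to interpolate from",
             "ctgdx_unusable_trace")
  if (length(obs) == length(fhr)) return(fhr)
  if (length(obs) == 1L) return(rep(fhr[obs], length(fhr)))
  stats::approx(obs, fhr[obs], xout = seq_along(fhr), method = "linear",
                rule = 2)$y
}

#' Smooth the uterine-contraction channel
#'
#' Centered moving average whose window spans `uc_smooth_window_s` seconds
#' (241 samples at 4 Hz, i.e. 240 sampling intervals), shrunk symmetrically
#' at the edges; length is preserved and a linear ramp is invariant in the
#' interior.
#'
#' @param uc numeric UC vector.
#' @param params a [cleaning_params()].
#' @return smoothed vector of the same length.
#' @export
smooth_uc <- function(uc, params = cleaning_params()) {
  centered_ma(uc, as.integer(params$uc_smooth_window_s * 4 / 2))
}

#' Extract the pre-delivery analysis segment
#'
#' Returns the samples whose times fall in the half-open window
#' `[delivery_time - segment_len - offset, delivery_time - offset)` —
#' by default the 30 minutes ending 20 minutes before delivery — exactly
#' `segment_len_s * 4` samples (7200 at defaults).  The returned trace's
#' `delivery_time` is re-expressed relative to the new start.
#'
#' @param trace a [ctg_trace()].
#' @param params a [cleaning_params()].
#' @return a [ctg_trace()] of exactly `segment_len_s * 4` samples, with
#'   attribute `segment_start` (1-based index of the first kept sample).
#' @export
extract_segment <- function(trace, params = cleaning_params()) {
  stopifnot(inherits(trace, "ctg_trace"))
  fs <- trace$sample_rate
  a <- trace$delivery_time - params$segment_len_s - params$segment_end_offset_s
  b <- trace$delivery_time - params$segment_end_offset_s
  t <- trace_times(trace)
  span_end <- (length(trace$fhr) - 1) / fs
  if (a < -1e-9 || span_end < b - 1 / fs - 1e-9) {
    missing_s <- max(0, -a) + max(0, (b - 1 / fs) - span_end)
    stop_ctg(sprintf(
      "insufficient pre-delivery coverage: trace misses %.2f s of the [%g, %g) s window",
      missing_s, a, b), "ctgdx_insufficient_span")
  }
  keep <- which(t >= a - 1e-9 & t < b - 1e-9)
  n_exp <- as.integer(params$segment_len_s * fs)
  keep <- keep[seq_len(min(length(keep), n_exp))]
  if (length(keep) != n_exp)
    stop_ctg(sprintf("insufficient pre-delivery coverage: %d of %d samples",
                     length(keep), n_exp), "ctgdx_insufficient_span")
  out <- ctg_trace(trace$fhr[keep], trace$uc[keep],
                   delivery_time = trace$delivery_time - t[keep[1]],
                   case_id = trace$case_id, sample_rate = fs)
  attr(out, "segment_start") <- keep[1]
  out
}

#' Clean a raw CTG trace
#'
#' Full cleaning chain, in the published order: discontinue at the first
#' >= 15 s zero run, mask remaining zeros and out-of-range values
#' (>= 200 / <= 50 bpm), mask > 25 bpm deviations from the 15 s local mean,
#' linearly interpolate all removed samples, smooth UC with a 60 s moving
#' average, then extract the 30-minute segment ending 20 minutes before
#' delivery.  Deterministic; cleaning an already-cleaned trace is a no-op.
#'
#' @param trace a raw [ctg_trace()] (or a `ctg_clean_trace`, returned
#'   unchanged).
#' @param params a [cleaning_params()].
#' @return a `ctg_clean_trace`: list with fields
#'   \describe{
#'     \item{trace}{the cleaned segment ([ctg_trace()], 7200 samples at
#'       defaults, no missing values)}
#'     \item{mask}{character per-sample flag, `"observed"` or
#'       `"interpolated"`, aligned to the segment}
#'     \item{truncation_point}{index where a qualifying zero run began, or `NA`}
#'     \item{segment_start}{index of the segment's first sample in the
#'       truncated full trace}
#'     \item{removed_full}{logical over the truncated full trace: which
#'       samples any rule removed}
#'     \item{removal_counts}{named counts per rule (zero, high, low, spike)}
#'   }
#' @export
clean <- function(trace, params = cleaning_params()) UseMethod("clean")

#' @export
clean.ctg_clean_trace <- function(trace, params = cleaning_params()) trace

#' @export
clean.ctg_trace <- function(trace, params = cleaning_params()) {
  tr <- truncate_at_zero_run(trace, params)
  trunc_at <- attr(tr, "truncation_point")
  fhr <- mask_invalid(tr$fhr, params)
  counts <- attr(fhr, "removal_counts")
  fhr <- mask_spikes(fhr, params)
  counts <- c(counts, attr(fhr, "removal_counts"))
  removed <- is.na(fhr) & !is.na(tr$fhr)
  fhr <- interpolate_gaps(fhr)
  uc <- smooth_uc(tr$uc, params)
  filled <- ctg_trace(fhr, uc, tr$delivery_time, tr$case_id, tr$sample_rate)
  seg <- extract_segment(filled, params)
  seg_start <- attr(seg, "segment_start")
  idx <- seq(seg_start, length.out = length(seg$fhr))
  structure(
    list(trace = seg,
         mask = ifelse(removed[idx], "interpolated", "observed"),
         truncation_point = trunc_at,
         segment_start = seg_start,
         removed_full = removed,
         removal_counts = counts),
    class = "ctg_clean_trace")
}

#' @export
print.ctg_clean_trace <- function(x, ...) {
  cat(sprintf("<ctg_clean_trace> case %s: %d-sample segment, %d interpolated (%.2f%%)\n",
              x$trace$case_id, length(x$trace$fhr),
              sum(x$mask == "interpolated"),
              100 * mean(x$mask == "interpolated")))
  cat("  removals:", paste(names(x$removal_counts), x$removal_counts,
                           sep = "=", collapse = " "),
      if (!is.na(x$truncation_point))
        sprintf("| discontinued at sample %d", x$truncation_point) else "",
      "\n")
  invisible(x)
}
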