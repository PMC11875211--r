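#' CTG trace objects
#'
#' A `ctg_trace` carries one cardiotocography recording: fetal heart rate
#' (FHR, beats per minute) sampled at a fixed 4 Hz together with the relative
#' strength of uterine contractions (UC), plus the delivery time in seconds
#' from the start of the trace.  Raw monitor exports encode signal dropout as
#' exact zeros; after cleaning, removed samples are `NA` (never 0).
#'
#' @param fhr numeric vector of FHR values in bpm. `NA` marks removed/masked
#'   samples; a raw trace contains no `NA`.
#' @param uc numeric vector of non-negative relative contraction strength,
#'   same length as `fhr`.
#' @param delivery_time delivery time in seconds from trace start (>= 0).
#' @param case_id opaque case identifier.
#' @param sample_rate samples per second; fixed at 4 for this device class.
#' @return an object of class `ctg_trace` with fields `case_id`,
#'   `sample_rate`, `fhr`, `uc`, `delivery_time`.
#' @examples
#' tr <- ctg_trace(fhr = rep(140, 40), uc = rep(10, 40), delivery_time = 10)
#' trace_times(tr)[1:4]
#' @export
ctg_trace <- function(fhr, uc, delivery_time, case_id = "case", sample_rate = 4) {
  fhr <- as.numeric(fhr)
  uc <- as.numeric(uc)
  if (length(fhr) != length(uc))
    stop_ctg("fhr and uc must have equal length", "ctgdx_invalid_trace")
  if (sample_rate != 4)
    stop_ctg("sample_rate must be 4 samples/second", "ctgdx_invalid_trace")
  if (!is.numeric(delivery_time) || length(delivery_time) != 1L ||
      is.na(delivery_time) || delivery_time < 0)
    stop_ctg("delivery_time must be a single non-negative number",
             "ctgdx_invalid_trace")
  if (any(uc < 0, na.rm = TRUE))
    stop_ctg("uc values must be non-negative", "ctgdx_invalid_trace")
  structure(
    list(case_id = as.character(case_id), sample_rate = 4,
         fhr = fhr, uc = uc, delivery_time = as.numeric(delivery_time)),
    class = "ctg_trace")
}

#' Sample times of a trace
#'
#' @param trace a [ctg_trace()].
#' @return numeric vector of sample times in seconds from trace start
#'   (first sample at 0, step 0.25 s).
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "ctg_trace"))
  (seq_along(trace$fhr) - 1) / trace$sample_rate
}

#' @export
length.ctg_trace <- function(x) length(x$fhr)

#' @export
print.ctg_trace <- function(x, ...) {
  n <- length(x$fhr)
  cat(sprintf("<ctg_trace> case %s: %d samples (%.1f s at %d Hz), delivery at %.1f s\n",
              x$case_id, n, n / x$sample_rate, x$sample_rate, x$delivery_time))
  cat(sprintf("  FHR: %d missing; UC range [%.1f, %.1f]\n",
              sum(is.na(x$fhr)), min(x$uc, na.rm = TRUE), max(x$uc, na.rm = TRUE)))
  invisible(x)
}

#' @exportS3Method base::all.equal
all.equal.ctg_trace <- function(target, current, ...) {
  a <- unclass(target); b <- unclass(current)
  all.equal(a, b, ...)
}
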