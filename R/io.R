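#' Read a CTG trace from CSV
#'
#' The on-disk dialect is a plain CSV with columns `time_s`, `fhr_bpm`, `uc`
#' preceded by a commented key:value header block carrying the trace
#' metadata (`case_id`, `sample_rate`, `delivery_time`).  It stands in for a
#' central-monitor export; real vendor formats are out of scope.  Empty
#' `fhr_bpm` cells are masked (`NA`) samples; the literal value 0 is raw
#' signal dropout and is kept as 0.
#'
#' @param path path to a trace CSV written by [write_trace_csv()] or
#'   following the same dialect.
#' @return a [ctg_trace()].
#' @seealso [write_trace_csv()]
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path))
    stop_ctg(sprintf("trace file not found: %s", path), "ctgdx_io_error")
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^#\\s*", "", l)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- lines[!hdr]
  if (length(body) < 1L)
    stop_ctg("trace file has no column header", "ctgdx_format_error")
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "numeric", blank.lines.skip = TRUE)
  for (col in c("time_s", "fhr_bpm", "uc"))
    if (!col %in% names(df))
      stop_ctg(sprintf("missing required column '%s'", col),
               "ctgdx_format_error")
  if (nrow(df) > 1L) {
    dt <- diff(df$time_s)
    bad <- which(abs(dt - 0.25) > 1e-6)
    if (length(bad))
      stop_ctg(sprintf(
        "sampling interval must be 0.25 s (4 Hz); first offending row %d (step %.4g s)",
        bad[1] + 1L, dt[bad[1]]), "ctgdx_format_error")
  }
  ctg_trace(fhr = df$fhr_bpm, uc = df$uc,
            delivery_time = as.numeric(meta$delivery_time %||% 0),
            case_id = meta$case_id %||% "case",
            sample_rate = as.numeric(meta$sample_rate %||% 4))
}

#' Write a CTG trace to CSV
#'
#' Inverse of [read_trace_csv()]; `read_trace_csv(write_trace_csv(x))`
#' reproduces `x` exactly, including masked (`NA`) samples, which are
#' serialized as empty cells so they can never be confused with the raw
#' dropout value 0.
#'
#' @param trace a [ctg_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ctg_trace"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_ctg(sprintf("cannot write trace to '%s': %s", path, conditionMessage(e)),
             "ctgdx_io_error"))
  on.exit(close(con))
  writeLines(c(sprintf("# case_id: %s", trace$case_id),
               sprintf("# sample_rate: %d", trace$sample_rate),
               sprintf("# delivery_time: %.10g", trace$delivery_time),
               "time_s,fhr_bpm,uc"), con)
  if (length(trace$fhr)) {
    t <- trace_times(trace)
    fhr <- ifelse(is.na(trace$fhr), "", format(trace$fhr, trim = TRUE, digits = 10))
    uc <- format(trace$uc, trim = TRUE, digits = 10)
    writeLines(paste(format(t, trim = TRUE, digits = 10), fhr, uc, sep = ","), con)
  }
  invisible(path)
}

#' Read cohort tables and join them into case records
#'
#' Joins the three per-case tables on `case_id`:
#' * `outcomes`: columns `case_id, apgar_1min, apgar_5min, ua_ph`
#' * `ratings`: long format, columns `case_id, rater_id, rater_class, judgment`
#'   (`judgment` in `{positive, negative}` or `{1, 0}`)
#' * `scores`: columns `case_id, dl_score, ml_call`
#'
#' One record is produced per case in the outcomes table.  Cases with no
#' ratings or no scores are kept with those channels empty/`NA` and counted
#' in the attributes `n_without_ratings` / `n_without_scores`.
#'
#' @param outcomes_path,ratings_path,scores_path CSV paths.
#' @return a list of case records (class `ctg_cohort`), each with fields
#'   `case_id`, `apgar_1min`, `apgar_5min`, `ua_ph`, `responses`
#'   (data.frame rater_id/rater_class/judgment), `dl_score`, `ml_call`.
#' @export
read_cohort_tables <- function(outcomes_path, ratings_path, scores_path) {
  outcomes <- utils::read.csv(outcomes_path)
  for (col in c("case_id", "apgar_1min", "apgar_5min", "ua_ph"))
    if (!col %in% names(outcomes))
      stop_ctg(sprintf("outcomes table: missing column '%s'", col),
               "ctgdx_format_error")
  if (anyDuplicated(outcomes$case_id))
    stop_ctg(sprintf("duplicate case_id in outcomes table: %s",
                     outcomes$case_id[duplicated(outcomes$case_id)][1]),
             "ctgdx_format_error")
  ratings <- utils::read.csv(ratings_path)
  scores <- utils::read.csv(scores_path)
  if (anyDuplicated(scores$case_id))
    stop_ctg("duplicate case_id in scores table", "ctgdx_format_error")
  if (nrow(ratings) && anyDuplicated(ratings[c("case_id", "rater_id")]))
    stop_ctg("duplicate (case_id, rater_id) in ratings table",
             "ctgdx_format_error")
  ratings$judgment <- normalize_judgment(ratings$judgment)

  recs <- lapply(seq_len(nrow(outcomes)), function(i) {
    id <- as.character(outcomes$case_id[i])
    resp <- ratings[as.character(ratings$case_id) == id,
                    c("rater_id", "rater_class", "judgment"), drop = FALSE]
    rownames(resp) <- NULL
    srow <- scores[as.character(scores$case_id) == id, , drop = FALSE]
    list(case_id = id,
         apgar_1min = outcomes$apgar_1min[i],
         apgar_5min = outcomes$apgar_5min[i],
         ua_ph = outcomes$ua_ph[i],
         responses = resp,
         dl_score = if (nrow(srow)) srow$dl_score[1] else NA_real_,
         ml_call = if (nrow(srow)) srow$ml_call[1] else NA_integer_)
  })
  structure(recs, class = "ctg_cohort",
            n_without_ratings = sum(vapply(recs, function(r) nrow(r$responses) == 0L, logical(1))),
            n_without_scores = sum(vapply(recs, function(r) is.na(r$dl_score), logical(1))))
}

normalize_judgment <- function(x) {
  if (is.numeric(x)) return(as.integer(x != 0))
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("positive", "pos", "1", "true"), 1L,
         ifelse(x %in% c("negative", "neg", "0", "false"), 0L, NA_integer_))
  if (anyNA(out))
    stop_ctg("judgment values must be positive/negative (or 1/0)",
             "ctgdx_format_error")
  out
}

#' Read a confusion-matrix fixture
#'
#' A fixture is a one-row CSV with columns `tp, fp, fn, tn` (non-negative
#' integers).  The four fixtures shipped under `inst/extdata/` are the
#' printed 2x2 distributions of each judgment method over the 489 evaluated
#' cases (31 asphyxia-positive / 458 negative).
#'
#' @param path fixture path.
#' @return a [confusion_matrix()].
#' @examples
#' p <- system.file("extdata", "table3_human.csv", package = "ctgdx")
#' read_confusion_fixture(p)
#' @export
read_confusion_fixture <- function(path) {
  df <- utils::read.csv(path)
  for (col in c("tp", "fp", "fn", "tn"))
    if (!col %in% names(df))
      stop_ctg(sprintf("confusion fixture: missing column '%s'", col),
               "ctgdx_format_error")
  confusion_matrix(df$tp[1], df$fp[1], df$fn[1], df$tn[1])
}

#' Write the per-case prediction table
#'
#' @param pred data.frame with columns `case_id, truth, human_ratio,
#'   dl_score, ml_call, fused_sum, fused_product`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(pred, path) {
  utils::write.csv(pred, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_prediction_table
#' @export
read_prediction_table <- function(path) {
  utils::read.csv(path)
}

#' Read a JSON run configuration
#'
#' Flat key/value JSON; unknown keys are kept so callers can nest module
#' parameter blocks (`trace`, `artifacts`, `outcome`, `raters`, `cleaning`).
#'
#' @param path JSON path.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
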