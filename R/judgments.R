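#' Label a neonatal outcome as asphyxia-positive
#'
#' A delivery is positive when the Apgar score is below 6 at 1 or 5
#' minutes, or the umbilical-artery pH is below 7.1.  All inequalities are
#' strict: Apgar 6 and pH 7.10 are negative.
#'
#' @param apgar_1min,apgar_5min integer Apgar scores in `[0, 10]`.
#' @param ua_ph umbilical-artery pH (plausible range `[6.5, 7.8]`).
#' @return logical vector (`TRUE` = asphyxia).
#' @examples
#' label_outcome(5, 9, 7.30)  # TRUE  (1-min Apgar branch)
#' label_outcome(6, 6, 7.10)  # FALSE (all boundaries are strict)
#' label_outcome(9, 9, 7.05)  # TRUE  (pH branch)
#' @export
label_outcome <- function(apgar_1min, apgar_5min, ua_ph) {
  if (anyNA(apgar_1min) || anyNA(apgar_5min) || anyNA(ua_ph))
    stop_ctg("unlabellable case: missing Apgar or pH field",
             "ctgdx_unlabellable")
  if (any(apgar_1min < 0 | apgar_1min > 10 | apgar_5min < 0 | apgar_5min > 10))
    stop_ctg("Apgar scores must lie in [0, 10]", "ctgdx_invalid_params")
  if (any(ua_ph < 6.5 | ua_ph > 7.8))
    stop_ctg("umbilical-artery pH outside plausible range [6.5, 7.8]",
             "ctgdx_invalid_params")
  apgar_1min < 6 | apgar_5min < 6 | ua_ph < 7.1
}

#' Binarize a model score at the 0.50 operating point
#'
#' A score of 0.50 and higher is a positive judgment (inclusive cutoff).
#'
#' @param score numeric in `[0, 1]`.
#' @param params a [decision_params()].
#' @return logical vector.
#' @export
binarize_dl <- function(score, params = decision_params()) {
  if (any(score < 0 | score > 1, na.rm = TRUE))
    stop_ctg("scores must lie in [0, 1]", "ctgdx_invalid_params")
  classify(score, params$dl_cutoff)
}

#' Decision cutoffs
#'
#' @param dl_cutoff model-score cutoff (the published operating point, 0.50).
#' @param human_cutoff cutoff on the human prediction ratio.
#' @param fused_sum_cutoff cutoff on the additive fusion score (range
#'   `[0, 2]`).
#' @param fused_product_cutoff cutoff on the product fusion score.
#' @return list of class `decision_params`.
#' @export
decision_params <- function(dl_cutoff = 0.50, human_cutoff = 0.50,
                            fused_sum_cutoff = 0.50,
                            fused_product_cutoff = 0.50) {
  structure(list(dl_cutoff = dl_cutoff, human_cutoff = human_cutoff,
                 fused_sum_cutoff = fused_sum_cutoff,
                 fused_product_cutoff = fused_product_cutoff),
            class = "decision_params")
}

#' Per-case human prediction ratio
#'
#' The fraction of rater responses judging the case positive, pooled over
#' rater classes by default or restricted to one class.  With
#' `type = "correct"` and a supplied truth label, returns instead the
#' fraction of responses that agree with the truth — the literal
#' "percentage of correct responses" variant, kept behind a flag for
#' sensitivity analysis because it leaks the label into the fused score.
#'
#' @param responses data.frame with columns `rater_id`, `rater_class`,
#'   `judgment` (1 = positive).
#' @param rater_class optional filter, `"obstetrician"` or `"midwife"`.
#' @param type `"positive"` (default, prediction ratio) or `"correct"`.
#' @param truth case truth label; required for `type = "correct"`.
#' @return a ratio in `[0, 1]`.
#' @export
human_ratio <- function(responses, rater_class = NULL,
                        type = c("positive", "correct"), truth = NULL) {
  type <- match.arg(type)
  if (!is.null(rater_class))
    responses <- responses[responses$rater_class == rater_class, , drop = FALSE]
  if (is.null(responses) || nrow(responses) == 0L)
    stop_ctg("prediction ratio requested for a case with no rater responses",
             "ctgdx_empty_responses")
  if (type == "positive") return(mean(responses$judgment == 1))
  if (is.null(truth))
    stop_ctg("type = 'correct' requires the truth label", "ctgdx_invalid_params")
  mean((responses$judgment == 1) == isTRUE(truth))
}

#' Fuse human and model scores
#'
#' `fuse_sum` is the additive combination (range `[0, 2]`; rank statistics
#' such as AUC are scale-invariant, thresholding uses its own cutoff).
#' `fuse_product` multiplies the two, so at any common cutoff in (0, 1] a
#' product-positive case is positive under both inputs individually —
#' false positives can only shrink, specificity can only rise.
#'
#' @param human_ratio,dl_score numerics in `[0, 1]`; `NA` propagates.
#' @return fused score.
#' @export
fuse_sum <- function(human_ratio, dl_score) {
  check_unit(human_ratio); check_unit(dl_score)
  human_ratio + dl_score
}

#' @rdname fuse_sum
#' @export
fuse_product <- function(human_ratio, dl_score) {
  check_unit(human_ratio); check_unit(dl_score)
  human_ratio * dl_score
}

check_unit <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop_ctg("fusion inputs must lie in [0, 1]", "ctgdx_invalid_params")
  invisible(x)
}

#' Threshold scores into binary calls
#'
#' @param scores numeric vector.
#' @param cutoff positive iff `score >= cutoff`.
#' @return logical vector (`NA` where the score is missing).
#' @export
classify <- function(scores, cutoff) scores >= cutoff

#' Build the per-case prediction table
#'
#' Combines truth labels, the pooled human prediction ratio, both model
#' channels and the two fused scores into one row per case.  Cases whose
#' outcome fields cannot be labelled, or that lack a channel, keep `NA` in
#' that channel and are excluded (with a message) from comparisons that
#' need it.
#'
#' @param cohort a `ctg_cohort` from [read_cohort_tables()], or a list with
#'   `cases` and `ratings` as returned by [generate_study_cohort()].
#' @param params a [decision_params()].
#' @return data.frame: `case_id, truth, human_ratio, dl_score, ml_call,
#'   fused_sum, fused_product`.
#' @export
prediction_table <- function(cohort, params = decision_params()) {
  if (inherits(cohort, "ctg_cohort")) {
    cases <- do.call(rbind, lapply(cohort, function(r)
      data.frame(case_id = r$case_id, apgar_1min = r$apgar_1min,
                 apgar_5min = r$apgar_5min, ua_ph = r$ua_ph,
                 dl_score = r$dl_score, ml_call = r$ml_call)))
    ratings <- do.call(rbind, lapply(cohort, function(r)
      if (nrow(r$responses)) cbind(case_id = r$case_id, r$responses)))
  } else {
    cases <- cohort$cases
    ratings <- cohort$ratings
  }
  truth <- if ("truth" %in% names(cases)) cases$truth
           else label_outcome(cases$apgar_1min, cases$apgar_5min, cases$ua_ph)
  hr <- vapply(cases$case_id, function(id) {
    resp <- ratings[ratings$case_id == id, , drop = FALSE]
    if (is.null(resp) || nrow(resp) == 0L) NA_real_ else mean(resp$judgment == 1)
  }, numeric(1))
  out <- data.frame(case_id = cases$case_id, truth = truth,
                    human_ratio = unname(hr),
                    dl_score = cases$dl_score, ml_call = cases$ml_call)
  out$fused_sum <- ifelse(is.na(out$human_ratio) | is.na(out$dl_score),
                          NA_real_, out$human_ratio + out$dl_score)
  out$fused_product <- ifelse(is.na(out$human_ratio) | is.na(out$dl_score),
                              NA_real_, out$human_ratio * out$dl_score)
  n_drop <- sum(is.na(out$human_ratio) | is.na(out$dl_score))
  if (n_drop > 0)
    message(sprintf("prediction_table: %d case(s) lack a channel and are excluded from fused comparisons", n_drop))
  out
}
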