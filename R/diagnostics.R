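#' Confusion matrix
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return object of class `confusion_matrix` with fields `tp, fp, fn, tn`
#'   and derived `total`, `positives`, `negatives`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop_ctg("confusion counts must be non-negative integers",
             "ctgdx_invalid_params")
  if (sum(counts) < 1)
    stop_ctg("empty matrix: all four confusion counts are zero",
             "ctgdx_invalid_params")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 total = tp + fp + fn + tn,
                 positives = tp + fn, negatives = fp + tn),
            class = "confusion_matrix")
}

#' Cross-classify binary calls against truth
#'
#' @param calls logical (or 0/1) predicted labels.
#' @param truths logical (or 0/1) true labels, same length.
#' @return a [confusion_matrix()].
#' @export
confusion <- function(calls, truths) {
  if (length(calls) != length(truths))
    stop_ctg("calls and truths must have equal length", "ctgdx_invalid_params")
  if (length(calls) < 1L)
    stop_ctg("need at least one case", "ctgdx_invalid_params")
  calls <- as.logical(calls); truths <- as.logical(truths)
  if (anyNA(calls) || anyNA(truths))
    stop_ctg("calls and truths must be complete (drop NA cases first)",
             "ctgdx_invalid_params")
  confusion_matrix(tp = sum(calls & truths), fp = sum(calls & !truths),
                   fn = sum(!calls & truths), tn = sum(!calls & !truths))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> n=%d  tp=%d fp=%d fn=%d tn=%d\n",
              x$total, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' The five table metrics plus the positive likelihood ratio
#'
#' Percent metrics from a 2x2 matrix: sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)`, precision `tp/(tp+fp)`, negative predictive
#' value `tn/(tn+fn)`, accuracy `(tp+tn)/total`, each times 100 and
#' reported half-up-rounded to 2 decimals (raw values are retained).
#' `lr_plus = sensitivity / (100 - specificity)`; `Inf` marks perfect
#' specificity.  A zero denominator flags the metric `NaN` (undefined)
#' rather than erroring.
#'
#' @param cm a [confusion_matrix()].
#' @return object of class `ctg_metrics`: list with `percent` (the five
#'   rounded percents), `raw` (unrounded), `lr_plus`, `undefined`
#'   (names of metrics with zero denominators).
#' @examples
#' metrics(confusion_matrix(7, 37, 24, 421))$percent  # the published human row
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe <- function(num, den) if (den == 0) NaN else 100 * num / den
  raw <- c(sensitivity = safe(cm$tp, cm$tp + cm$fn),
           specificity = safe(cm$tn, cm$tn + cm$fp),
           precision = safe(cm$tp, cm$tp + cm$fp),
           npv = safe(cm$tn, cm$tn + cm$fn),
           accuracy = safe(cm$tp + cm$tn, cm$total))
  lr_plus <- if (is.nan(raw["specificity"]) || is.nan(raw["sensitivity"])) NaN
             else if (raw["specificity"] >= 100) Inf
             else unname(raw["sensitivity"] / (100 - raw["specificity"]))
  structure(list(percent = round_half_up(raw, 2), raw = raw,
                 lr_plus = lr_plus,
                 undefined = names(raw)[is.nan(raw)]),
            class = "ctg_metrics")
}

#' @export
print.ctg_metrics <- function(x, ...) {
  p <- x$percent
  cat(sprintf("sens %.2f%%  spec %.2f%%  prec %.2f%%  npv %.2f%%  acc %.2f%%  LR+ %.3f\n",
              p["sensitivity"], p["specificity"], p["precision"],
              p["npv"], p["accuracy"], x$lr_plus))
  invisible(x)
}

#' ROC curve
#'
#' Operating points at every distinct score value (calls positive at
#' `score >= t`), plus the trivial all-negative point.  Because thresholds
#' sit exactly at distinct values, the trapezoidal area under the points
#' equals the midrank (Mann-Whitney) AUC, including under ties.
#'
#' @param scores finite numeric scores (higher = more positive).
#' @param truths logical truth labels; both classes must be present.
#' @return object of class `ctg_roc`: data.frame `points`
#'   (`threshold, fpr, tpr`), `auc`, `n_pos`, `n_neg`, and the
#'   Hanley-McNeil test fields `se`, `z`, `p_two_sided` (vs AUC 0.5).
#' @export
roc <- function(scores, truths) {
  truths <- as.logical(truths)
  ok <- !is.na(scores) & !is.na(truths)
  scores <- scores[ok]; truths <- truths[ok]
  if (!any(truths) || all(truths))
    stop_ctg("ROC needs at least one positive and one negative case",
             "ctgdx_single_class")
  if (any(!is.finite(scores)))
    stop_ctg("scores must be finite", "ctgdx_invalid_params")
  n_pos <- sum(truths); n_neg <- sum(!truths)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(truths & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!truths & scores >= t) / n_neg, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  test <- auc_test(auc, n_pos, n_neg)
  structure(c(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
              test),
            class = "ctg_roc")
}

#' @export
print.ctg_roc <- function(x, ...) {
  cat(sprintf("<ctg_roc> AUC %.4f (n_pos %d, n_neg %d), SE %.4f, z %.3f, p %.4g\n",
              x$auc, x$n_pos, x$n_neg, x$se, x$z, x$p_two_sided))
  invisible(x)
}

#' AUC significance against chance
#'
#' Hanley-McNeil standard error of an empirical AUC, with a two-sided
#' normal test of the null AUC = 0.5.
#'
#' @param auc empirical AUC in `[0, 1]`.
#' @param n_pos,n_neg class sizes (>= 1 each).
#' @return list with `se`, `z`, `p_two_sided`.
#' @export
auc_test <- function(auc, n_pos, n_neg) {
  if (n_pos < 1 || n_neg < 1)
    stop_ctg("both classes must be non-empty", "ctgdx_invalid_params")
  if (auc < 0 || auc > 1)
    stop_ctg("auc must lie in [0, 1]", "ctgdx_invalid_params")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- if (se == 0) Inf * sign(auc - 0.5) else (auc - 0.5) / se
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  if (auc == 0.5) p <- 1
  list(se = se, z = z, p_two_sided = p)
}

#' Per-threshold positive likelihood ratios along a ROC curve
#'
#' `LR+(t) = tpr(t) / fpr(t)`; points with `fpr = 0` get an `Inf` marker
#' (and `NaN` at the degenerate origin).  The maximum is taken over finite
#' values by default; `include_infinite = TRUE` lets a zero-false-positive
#' operating point dominate.
#'
#' @param roc_result a [roc()] result.
#' @param include_infinite include infinite LR+ values in the maximum.
#' @return list with `lr_plus` (per operating point), `max_lr_plus`, and
#'   `range` (c(min, max) over finite values).
#' @export
likelihood_ratios <- function(roc_result, include_infinite = FALSE) {
  stopifnot(inherits(roc_result, "ctg_roc"))
  p <- roc_result$points
  lr <- ifelse(p$fpr > 0, p$tpr / p$fpr,
               ifelse(p$tpr > 0, Inf, NaN))
  finite <- lr[is.finite(lr)]
  mx <- if (include_infinite && any(is.infinite(lr)) && any(lr == Inf)) Inf
        else if (length(finite)) max(finite) else NaN
  list(lr_plus = lr, max_lr_plus = mx,
       range = if (length(finite)) range(finite) else c(NaN, NaN))
}

#' Evaluate every judgment method over a prediction table
#'
#' For each available channel — `human` (prediction ratio), `ml` (binary
#' call only), `dl` (score), `fused_sum`, `fused_product` — computes the
#' confusion matrix at its cutoff, the five table metrics, and, where a
#' graded score exists, the ROC with AUC significance and per-threshold
#' likelihood ratios.  Cases missing a channel are dropped from that
#' channel only; missing channels are skipped with a warning.
#'
#' @param pred prediction table from [prediction_table()].
#' @param params a [decision_params()].
#' @return named list of per-method results (class `ctg_evaluation`), each
#'   with `n`, `confusion`, `metrics`, and (scored channels) `roc`, `lr`.
#' @export
evaluate_methods <- function(pred, params = decision_params()) {
  channels <- list(
    human = list(col = "human_ratio", cutoff = params$human_cutoff, graded = TRUE),
    ml = list(col = "ml_call", cutoff = 0.5, graded = FALSE),
    dl = list(col = "dl_score", cutoff = params$dl_cutoff, graded = TRUE),
    fused_sum = list(col = "fused_sum", cutoff = params$fused_sum_cutoff, graded = TRUE),
    fused_product = list(col = "fused_product", cutoff = params$fused_product_cutoff, graded = TRUE))
  out <- list()
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!ch$col %in% names(pred) || all(is.na(pred[[ch$col]]))) {
      warning(sprintf("channel '%s' missing from prediction table; skipped", nm))
      next
    }
    ok <- !is.na(pred[[ch$col]]) & !is.na(pred$truth)
    x <- pred[[ch$col]][ok]; truth <- as.logical(pred$truth[ok])
    cm <- confusion(classify(x, ch$cutoff), truth)
    res <- list(n = sum(ok), confusion = cm, metrics = metrics(cm))
    if (ch$graded && any(truth) && !all(truth)) {
      res$roc <- roc(x, truth)
      res$lr <- likelihood_ratios(res$roc)
    }
    out[[nm]] <- res
  }
  structure(out, class = "ctg_evaluation")
}

#' @export
print.ctg_evaluation <- function(x, ...) {
  cat(sprintf("%-14s %5s %8s %8s %8s %8s %8s %8s\n", "method", "n",
              "sens%", "spec%", "prec%", "npv%", "acc%", "AUC"))
  for (nm in names(x)) {
    p <- x[[nm]]$metrics$percent
    cat(sprintf("%-14s %5d %8.2f %8.2f %8.2f %8.2f %8.2f %8s\n", nm,
                x[[nm]]$n, p["sensitivity"], p["specificity"], p["precision"],
                p["npv"], p["accuracy"],
                if (!is.null(x[[nm]]$roc)) sprintf("%.4f", x[[nm]]$roc$auc) else "-"))
  }
  invisible(x)
}

#' Serialize an evaluation to JSON
#'
#' @param ev a `ctg_evaluation` from [evaluate_methods()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(ev, path) {
  enc <- lapply(ev, function(m) {
    out <- list(n = m$n,
                confusion = m$confusion[c("tp", "fp", "fn", "tn")],
                percent = as.list(m$metrics$percent),
                raw = as.list(m$metrics$raw),
                lr_plus = if (is.finite(m$metrics$lr_plus)) m$metrics$lr_plus else
                  as.character(m$metrics$lr_plus))
    if (!is.null(m$roc))
      out$roc <- list(auc = m$roc$auc, se = m$roc$se, z = m$roc$z,
                      p_two_sided = m$roc$p_two_sided,
                      max_lr_plus = m$lr$max_lr_plus)
    out
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
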