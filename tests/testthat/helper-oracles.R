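# Fixture builders and independent brute-force oracles.
# Oracles deliberately use naive loops, so they share no code with the
# implementation they check.

make_flat_trace <- function(n = 400, fhr = 140, uc = 10, delivery = NULL) {
  ctg_trace(fhr = rep(fhr, n), uc = rep(uc, n),
            delivery_time = delivery %||% (n / 4), case_id = "t")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a trace long enough to clean with defaults: covers [0, delivery] with
# delivery at duration_s
make_long_trace <- function(duration_s = 3600, fhr = 140, uc = 10) {
  n <- duration_s * 4
  ctg_trace(rep(fhr, n), rep(uc, n), delivery_time = duration_s, case_id = "t")
}

# oracle: first index starting a run of >= min_run consecutive zeros, else NA
oracle_first_zero_run <- function(x, min_run) {
  n <- length(x)
  i <- 1L
  while (i <= n) {
    if (!is.na(x[i]) && x[i] == 0) {
      j <- i
      while (j < n && !is.na(x[j + 1]) && x[j + 1] == 0) j <- j + 1L
      if (j - i + 1L >= min_run) return(i)
      i <- j + 1L
    } else i <- i + 1L
  }
  NA_integer_
}

# oracle: spike decisions by direct windowed-mean scan (window of
# half*2 + 1 samples centered on i, clipped at edges, NAs excluded,
# sample included in its own mean)
oracle_spike_mask <- function(x, half = 30L, max_dev = 25) {
  n <- length(x)
  out <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    w <- x[max(1L, i - half):min(n, i + half)]
    w <- w[!is.na(w)]
    if (length(w) && abs(x[i] - mean(w)) > max_dev) out[i] <- TRUE
  }
  out
}

# oracle: centered moving average by direct loop
oracle_centered_ma <- function(x, half) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- mean(x[(i - h):(i + h)])
  }
  out
}

# oracle: AUC by exhaustive pair counting (concordant + half ties over
# all positive x negative pairs)
oracle_auc <- function(scores, truths) {
  pos <- scores[as.logical(truths)]
  neg <- scores[!as.logical(truths)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# maximal TRUE runs as a data.frame(start, end), 1-based inclusive
true_runs_df <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# value of a cleaned trace at full-trace indices (NA outside the segment)
clean_value_at <- function(cl, idx_full) {
  rel <- idx_full - cl$segment_start + 1L
  out <- rep(NA_real_, length(idx_full))
  ok <- rel >= 1L & rel <= length(cl$trace$fhr)
  out[ok] <- cl$trace$fhr[rel[ok]]
  out
}

# random small score/truth instance with ties (both classes guaranteed)
random_roc_instance <- function(n_max = 50) {
  n <- sample(3:n_max, 1)
  scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
  truths <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
  list(scores = scores, truths = truths)
}
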