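# internal helpers shared across modules

# Round half away from zero to `digits` decimals (printed tables use
# commercial rounding, not banker's). Small eps guards binary representation.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Run a block with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Centered moving average with an odd window of `2*half + 1` samples,
# shrunk symmetrically at the edges so the window stays centered.
centered_ma <- function(x, half) {
  n <- length(x)
  if (half < 1L || n == 0L) return(x)
  cs <- cumsum(c(0, x))
  h <- pmin(half, seq_len(n) - 1L, n - seq_len(n))
  lo <- seq_len(n) - h
  hi <- seq_len(n) + h
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Maximal runs of TRUE in a logical vector: data.frame(start, end, length),
# 1-based inclusive indices.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctg <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ctgdx_error")))
}
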