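test_that("zero-run discontinuation: >= 15.0 s cuts, shorter is left", {
  base <- rep(140, 1000)
  x <- base; x[401:460] <- 0                     # 60 samples = 15.0 s
  tr <- ctg_trace(x, rep(1, 1000), 250)
  out <- truncate_at_zero_run(tr)
  expect_length(out, 400)
  expect_equal(attr(out, "truncation_point"), 401L)

  x <- base; x[401:459] <- 0                     # 59 samples = 14.75 s
  out <- truncate_at_zero_run(ctg_trace(x, rep(1, 1000), 250))
  expect_length(out, 1000)
  expect_true(is.na(attr(out, "truncation_point")))

  out <- truncate_at_zero_run(ctg_trace(base, rep(1, 1000), 250))
  expect_length(out, 1000)                       # no zeros -> identity

  x <- base; x[1:60] <- 0                        # run at the very start
  expect_error(truncate_at_zero_run(ctg_trace(x, rep(1, 1000), 250)),
               "unusable", class = "ctgdx_unusable_trace")
})

test_that("truncation point matches a brute-force run-length scan", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(200:600, 1)
    x <- rep(140, n)
    for (k in seq_len(sample(0:4, 1))) {
      s <- sample(n - 80, 1)
      x[s:min(n, s + sample(10:80, 1))] <- 0
    }
    want <- oracle_first_zero_run(x, 60L)
    got <- attr(truncate_at_zero_run(ctg_trace(x, rep(1, n), n / 4)),
                "truncation_point")
    if (is.na(want) || want == 1L) {
      # implementation errors when the cut would leave nothing
      if (!is.na(want) && want == 1L)
        expect_error(truncate_at_zero_run(ctg_trace(x, rep(1, n), n / 4)))
      else expect_true(is.na(got))
    } else expect_equal(got, want)
  }
})

test_that("range mask boundaries are inclusive exactly as printed", {
  x <- c(140, 200, 199, 50, 51, 0, 140)
  out <- mask_invalid(x)
  expect_equal(is.na(out), c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(attr(out, "removal_counts"), c(zero = 1L, high = 1L, low = 1L))
  # all in (50, 200), no zeros -> identity
  clean_x <- seq(51, 199, length.out = 20)
  expect_equal(as.numeric(mask_invalid(clean_x)), clean_x)
})

test_that("spike mask: > 25 bpm from the 15 s window mean, strict boundary", {
  x <- rep(140, 200); x[100] <- 166
  out <- mask_spikes(x)
  expect_true(is.na(out[100]))
  expect_equal(sum(is.na(out)), 1L)
  expect_equal(attr(out, "removal_counts"), c(spike = 1L))

  # exact-boundary construction: 61 samples, window mean exactly 135,
  # deviation of both extreme samples exactly 25 -> kept (strict >)
  y <- rep(135, 61); y[1] <- 110; y[31] <- 160
  expect_false(anyNA(mask_spikes(y)))
  y[31] <- 161                                  # now 25.98 > 25 -> masked
  expect_true(is.na(mask_spikes(y)[31]))

  expect_false(anyNA(mask_spikes(rep(140, 500)))) # constant -> identity
})

test_that("spike decisions equal the brute-force windowed-mean oracle", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(50:300, 1)
    x <- 140 + cumsum(rnorm(n, 0, 2))
    x[sample(n, sample(0:5, 1))] <- sample(c(60, 120, 190, 195), 1)
    x[sample(n, sample(0:3, 1))] <- NA           # pre-masked samples
    got <- is.na(mask_spikes(x)) & !is.na(x)
    expect_identical(got, oracle_spike_mask(x))
  }
})

test_that("linear interpolation fills gaps; edges extend nearest value", {
  expect_equal(interpolate_gaps(c(140, NA, NA, 146)), c(140, 142, 144, 146))
  expect_equal(interpolate_gaps(c(NA, 140, 150)), c(140, 140, 150))
  x <- c(130, 140, 150)
  expect_equal(interpolate_gaps(x), x)           # no gaps -> identity
  expect_error(interpolate_gaps(c(NA_real_, NA_real_)), "unusable",
               class = "ctgdx_unusable_trace")
})

test_that("UC smoothing: length-preserving centered mean over 60 s", {
  expect_equal(smooth_uc(rep(20, 1000)), rep(20, 1000))
  ramp <- seq(0, 100, length.out = 2000)
  got <- smooth_uc(ramp)
  expect_equal(got[200:1800], ramp[200:1800])    # linear interior unchanged
  imp <- rep(0, 1000); imp[500] <- 1
  got <- smooth_uc(imp)
  expect_equal(got[500], 1 / 241)                # 241-sample window spans 60 s
  expect_equal(sum(got[380:620] > 0), 241)
  expect_equal(got, oracle_centered_ma(imp, 120L))
})

test_that("segment extraction returns exactly the stated window", {
  n <- 3600 * 4 + 1
  tr <- ctg_trace(rep(140, n), rep(1, n), delivery_time = 3600)
  seg <- extract_segment(tr)
  expect_length(seg, 7200)
  t0 <- (attr(seg, "segment_start") - 1) / 4
  expect_equal(t0, 600)                          # [600, 2400) s
  expect_equal(t0 + (7200 - 1) / 4, 2399.75)
  expect_equal(seg$delivery_time, 3000)

  # trace spanning exactly the window
  m <- 7200
  tr2 <- ctg_trace(rep(140, m), rep(1, m), delivery_time = 3000)
  seg2 <- extract_segment(tr2)
  expect_length(seg2, 7200)
  expect_equal(seg2$fhr, tr2$fhr)

  # ends 25 min before delivery -> insufficient
  tr3 <- ctg_trace(rep(140, 8000), rep(1, 8000), delivery_time = 3500)
  expect_error(extract_segment(tr3), "insufficient pre-delivery coverage",
               class = "ctgdx_insufficient_span")
})

test_that("clean() composes the stages and is idempotent and complete", {
  tr <- make_long_trace()
  cl <- clean(tr)
  expect_s3_class(cl, "ctg_clean_trace")
  expect_length(cl$trace, 7200)
  expect_false(anyNA(cl$trace$fhr))
  expect_true(all(cl$mask %in% c("observed", "interpolated")))
  # artifact-free trace -> identity up to cropping
  expect_true(all(cl$mask == "observed"))
  expect_equal(cl$trace$fhr, rep(140, 7200))
  # idempotence
  expect_identical(clean(cl), cl)
  # and the masking stages find nothing left to remove in a cleaned trace
  expect_equal(sum(attr(mask_invalid(cl$trace$fhr), "removal_counts")), 0L)
  expect_equal(unname(attr(mask_spikes(cl$trace$fhr), "removal_counts")), 0L)
})

test_that("cleaning a corrupted trace recovers exactly the ledger", {
  tr <- generate_clean_trace(trace_gen_params(decel_rate_per_h = 2,
                                              decel_lag_s = 20), seed = 11)
  bad <- corrupt_trace(tr, artifact_params(), seed = 12)
  cl <- clean(bad)
  led <- attr(bad, "artifact_ledger")
  expect_setequal(which(cl$removed_full), led$index)
  # mask over the segment = ledger indices that fall inside the segment
  seg_idx <- seq(cl$segment_start, length.out = 7200)
  expect_identical(cl$mask == "interpolated",
                   seg_idx %in% led$index)
  # interpolated values stay within the local range of the clean signal
  gaps <- true_runs_df(cl$removed_full)
  for (g in seq_len(nrow(gaps))) {
    lo <- max(1L, gaps$start[g] - 1L); hi <- min(length(tr$fhr), gaps$end[g] + 1L)
    local_rng <- range(tr$fhr[lo:hi])
    filled <- clean_value_at(cl, gaps$start[g]:gaps$end[g])
    filled <- filled[!is.na(filled)]
    if (length(filled))
      expect_true(all(filled >= local_rng[1] - 1e-9 &
                        filled <= local_rng[2] + 1e-9))
  }
})
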