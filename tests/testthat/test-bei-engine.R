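fs_t <- 128
tpl_t <- synthetic_erp_template(fs_t)

test_that("delta bandpass keeps the band and kills DC and high frequencies", {
  t <- seq(0, 10, by = 1 / 256)
  inband <- eeg_recording(sin(2 * pi * 2.5 * t), 256)
  y <- bandpass_delta(inband)
  mid <- 1000:1500
  expect_gt(max(abs(y$samples[mid])), 0.95)

  high <- eeg_recording(sin(2 * pi * 20 * t), 256)
  expect_lt(max(abs(bandpass_delta(high)$samples[mid])), 0.1)

  dc <- eeg_recording(rep(5, length(t)), 256)
  expect_lt(max(abs(bandpass_delta(dc)$samples)) / 5, 1e-3)  # > 60 dB down

  short <- eeg_recording(rnorm(256), 256)  # 1 s < 3 s warm-up
  expect_error(bandpass_delta(short), "warm-up")
  expect_error(bandpass_delta(eeg_recording(rnorm(50), 6)), "too low")
})

test_that("unit-range normalization maps extremes to -1/+1 and keeps order", {
  expect_equal(normalize_unit_range(c(0, 2, 4)), c(-1, 0, 1))
  expect_equal(normalize_unit_range(c(-5, 5)), c(-1, 1))
  x <- rnorm(100)
  expect_equal(order(normalize_unit_range(x)), order(x))
  expect_error(normalize_unit_range(c(3, 3, 3)),
               class = "braindex_degenerate_segment")
})

test_that("window distances follow the mean-absolute formula", {
  w <- tpl_t$values
  d <- window_distance(w, tpl_t)
  expect_equal(unname(d["d_template"]), 0)
  d2 <- window_distance(-w, tpl_t)
  expect_equal(unname(d2["d_opposite"]), 0)
  expect_equal(unname(d2["d_template"]), mean(2 * abs(w)))
  # constant offset: d_template equals the offset exactly
  d3 <- window_distance(w + 0.1, tpl_t)
  expect_equal(unname(d3["d_template"]), 0.1)
  expect_error(window_distance(w[-1], tpl_t), "length")
})

test_that("noise ratio is the rectified-amplitude CV with degenerate rules", {
  expect_equal(noise_ratio(rep(2, 100)), 0)           # steady signal
  expect_equal(noise_ratio(numeric(100)), Inf)        # all-zero -> noisy
  # sparse bursts: sd(|w|) well above mean(|w|)
  burst <- c(rep(0.01, 180), rep(10, 12))
  expect_gt(noise_ratio(burst), 1)
  # crafted ratio: verify the formula directly
  x <- c(rep(1, 50), rep(4, 10))
  expect_equal(noise_ratio(x), sd(abs(x)) / mean(abs(x)))
})

test_that("a segment of back-to-back templates saturates at BEI = 1", {
  seg <- tiled_template_recording(tpl_t, 10)
  res <- scan_segment(seg, tpl_t)
  expect_true(res$valid)
  expect_equal(res$bei, 1)
  expect_gt(res$matches, 0)
})

test_that("two non-overlapping artifact bursts invalidate a segment", {
  spec <- synth_spec(duration_s = 10, fs = fs_t, embed_rate = 0,
                     artifact_rate_per_min = 0)
  bg <- gen_background(spec, seed = 31)
  x <- bg$samples
  np <- round(0.5 * fs_t)
  pulse <- 200 * sin(2 * pi * 2 * (0:(np - 1)) / fs_t)
  for (at in c(2, 7)) {  # bursts 5 s apart: windows cannot overlap
    i0 <- round(at * fs_t)
    x[i0:(i0 + np - 1)] <- x[i0:(i0 + np - 1)] + pulse
  }
  res <- scan_segment(eeg_recording(x, fs_t), tpl_t)
  expect_gte(res$rejected_windows, 2)
  expect_false(res$valid)
  expect_true(is.na(res$bei))
})

test_that("a constant segment is returned invalid rather than erroring", {
  res <- scan_segment(eeg_recording(rep(1, 10 * fs_t), fs_t), tpl_t)
  expect_false(res$valid)
})

test_that("minute aggregation takes the median of valid segments with a >=3 rule", {
  seg <- function(bei, valid) {
    r <- braindex:::segment_result(0, valid = valid, bei = bei)
    r$matches <- 1L; r
  }
  six <- do.call(rbind, list(seg(0.2, TRUE), seg(0.4, TRUE), seg(0.6, TRUE),
                             seg(NA, FALSE), seg(NA, FALSE), seg(NA, FALSE)))
  expect_equal(minute_bei(six), 0.4)
  two <- do.call(rbind, list(seg(0.2, TRUE), seg(0.4, TRUE), seg(NA, FALSE),
                             seg(NA, FALSE), seg(NA, FALSE), seg(NA, FALSE)))
  expect_true(is.na(minute_bei(two)))
  all_eq <- do.call(rbind, rep(list(seg(0.5, TRUE)), 6))
  expect_equal(minute_bei(all_eq), 0.5)
  expect_error(minute_bei(six[1:5, ]), "expected 6")
})

test_that("emissions follow the 10 s cadence starting at 60 s", {
  spec <- synth_spec(duration_s = 120, fs = fs_t, embed_rate = 1,
                     artifact_rate_per_min = 0)
  g <- gen_recording(spec, tpl_t, seed = 7)
  tr <- stream_bei(g$recording, tpl_t)
  expect_equal(tr$times_s, seq(60, 120, by = 10))
  expect_length(tr$values, 7)
  expect_true(all(diff(tr$times_s) == 10))
  ok <- !is.na(tr$values)
  expect_true(all(tr$values[ok] >= 0 & tr$values[ok] <= 1))
})

test_that("a recording shorter than one analysis window gives an empty trace", {
  spec <- synth_spec(duration_s = 50, fs = fs_t, embed_rate = 0,
                     artifact_rate_per_min = 0)
  rec <- gen_background(spec, seed = 2)
  expect_warning(tr <- stream_bei(rec, tpl_t), "shorter")
  expect_length(tr$values, 0)
})

test_that("chunked feeding reproduces the batch trace exactly", {
  spec <- synth_spec(duration_s = 90, fs = fs_t, embed_rate = 1.5,
                     artifact_rate_per_min = 2)
  g <- gen_recording(spec, tpl_t, seed = 11)
  batch <- stream_bei(g$recording, tpl_t)
  for (chunk in c(64, 1280, 7001)) {
    st <- bei_stream(tpl_t, fs = fs_t)
    x <- g$recording$samples
    for (i0 in seq(1, length(x), by = chunk))
      st$feed(x[i0:min(i0 + chunk - 1, length(x))])
    tr <- st$trace()
    expect_identical(tr$values, batch$values)
    expect_identical(tr$times_s, batch$times_s)
  }
})

test_that("scan results agree with the brute-force interval-bookkeeping oracle", {
  fs <- 64
  tpl <- synthetic_erp_template(fs)
  for (s in 1:8) {
    spec <- synth_spec(duration_s = 10, fs = fs,
                       embed_rate = (s %% 4), embed_amplitude_uV = 15,
                       artifact_rate_per_min = 6 * (s %% 2),
                       artifact_amplitude_uV = 150)
    g <- gen_recording(spec, tpl, seed = 100 + s)
    got <- scan_segment(g$recording, tpl)
    ref <- oracle_scan_segment(g$recording, tpl)
    expect_equal(got$matches, ref$matches)
    expect_equal(got$nomatches, ref$nomatches)
    expect_equal(got$rejected_windows, ref$rejected)
    expect_equal(got$valid, ref$valid)
    expect_equal(got$bei, ref$bei)
  }
})

test_that("trace CSV round-trips including missing values", {
  tr <- braindex:::bei_trace(c(60, 70, 80), c(0.5, NA, 0.25), c(6L, 2L, 5L),
                             braindex:::segment_result(numeric(0))[0, ],
                             engine_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$values, tr$values)
  expect_equal(back$times_s, tr$times_s)
})

test_that("engine configuration validates its structural constraints", {
  expect_error(engine_config(window_s = 55), "integer multiple")
  expect_error(engine_config(match_threshold = 0))
  cfg <- engine_config()
  expect_equal(cfg$window_s / cfg$segment_s, 6)
})
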