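test_that("band-pass suppresses DC and passes in-band tones", {
  dc <- signal_recording(matrix(rep(1, 10000), 1L), 2000)
  expect_gt(attenuation_db(dc, bandpass_filter(dc)), 60)
  t200 <- tone_recording(200)
  expect_lt(abs(attenuation_db(t200, bandpass_filter(t200))), 3)
  expect_error(bandpass_filter(tone_recording(10), low = 100, high = 50),
               "out of order")
  expect_error(bandpass_filter(tone_recording(10), high = 1200),
               "Nyquist")
})

test_that("notch removes the line frequency and little else", {
  t50 <- tone_recording(50)
  expect_gt(attenuation_db(t50, notch_filter(t50)), 20)
  t200 <- tone_recording(200)
  expect_lt(abs(attenuation_db(t200, notch_filter(t200))), 1)
  expect_error(notch_filter(tone_recording(10), freq = 1500), "Nyquist")
})

test_that("filtering is linear and the chain preserves shape", {
  withr::with_seed(12, x <- matrix(rnorm(3 * 4000), 3L))
  rec <- signal_recording(x, 2000, annotations = rep("rest", 4000))
  a <- bandpass_filter(signal_recording(5 * x, 2000))
  b <- bandpass_filter(rec)
  expect_lt(max(abs(a$data - 5 * b$data)), 1e-9)
  chain <- resample_recording(notch_filter(bandpass_filter(rec)), 1000)
  expect_identical(nrow(chain$data), 3L)
  expect_identical(ncol(chain$data), 2000L)
  expect_identical(chain$channel_names, rec$channel_names)
  expect_length(chain$annotations, 2000L)
  chain2 <- resample_recording(notch_filter(bandpass_filter(rec)), 1000)
  expect_identical(chain$data, chain2$data) # deterministic
})

test_that("resampling scales the sample count and suppresses aliases", {
  rec <- signal_recording(matrix(rnorm(2000), 1L), 2000)
  down <- resample_recording(rec, 1000)
  expect_identical(ncol(down$data), 1000L)
  expect_equal(down$rate, 1000)
  expect_identical(resample_recording(rec, 2000), rec) # identity
  # content above the target Nyquist must not fold back in
  t700 <- tone_recording(700)
  folded <- resample_recording(t700, 1000)
  expect_gt(10 * log10(interior_power(t700) / interior_power(folded)), 20)
})

test_that("window segmentation counts, boundaries and majority labels", {
  rec <- signal_recording(matrix(seq_len(1000), 1L), 1000)
  seg <- segment_windows(rec, window_spec(50, 15))
  expect_identical(dim(seg$windows)[1L], 64L) # floor(950/15) + 1
  # no window reads past the recording
  expect_true(all(seg$starts + 50L - 1L <= 1000L))
  expect_identical(dim(segment_windows(
    signal_recording(matrix(rnorm(50), 1L), 1000),
    window_spec(50, 15))$windows)[1L], 1L)
  expect_identical(dim(segment_windows(
    signal_recording(matrix(rnorm(49), 1L), 1000),
    window_spec(50, 15))$windows)[1L], 0L)
  expect_error(window_spec(50, 60), "increment")
  # majority labeling with rest-dropping
  ann <- c(rep("rest", 30), rep("move", 70))
  rec2 <- signal_recording(matrix(rnorm(100), 1L), 100, annotations = ann)
  seg2 <- segment_windows(rec2, window_spec(20, 10))
  expect_false(any(seg2$labels == "rest"))
  expect_true(all(seg2$labels == "move"))
  # tie (10 rest / 10 move in a window) resolves to the earlier label in
  # sorted class order ("move" < "rest"), so the boundary window is kept
  expect_true(21L %in% seg2$starts)
})

test_that("annotations survive resampling by nearest index", {
  ann <- c(rep("a", 1000), rep("b", 1000))
  rec <- signal_recording(matrix(rnorm(2000), 1L), 2000, annotations = ann)
  down <- resample_recording(rec, 1000)
  expect_identical(down$annotations, c(rep("a", 500), rep("b", 500)))
})
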