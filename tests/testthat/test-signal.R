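make_sine_rec <- function(freq, amp = 100, fs = 12500, duration = 1) {
  t <- (seq_len(fs * duration) - 1) / fs
  voltage_recording(matrix(amp * sin(2 * pi * freq * t), nrow = 1),
                    sampling_rate = fs)
}

test_that("band-pass passes the spike band and rejects LFP frequencies", {
  spec <- filter_spec()
  # 1000 Hz: passband center, amplitude preserved within 5%
  out <- bandpass_filter(make_sine_rec(1000), spec)
  mid <- out$samples[1, 3000:10000]  # away from edges
  expect_lt(abs(max(mid) - 100) / 100, 0.05)
  # 10 Hz: deep in the stopband, < 5% passes
  out <- bandpass_filter(make_sine_rec(10), spec)
  expect_lt(max(abs(out$samples[1, 3000:10000])), 5)
})

test_that("band-pass of an all-zero trace is all zeros", {
  rec <- voltage_recording(matrix(0, nrow = 2, ncol = 5000),
                           sampling_rate = 12500)
  out <- bandpass_filter(rec)
  expect_equal(out$samples, rec$samples)
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- make_sine_rec(100, fs = 5000)
  expect_error(bandpass_filter(rec, filter_spec(low_pass = 3000)),
               "Nyquist")
})

test_that("MAD noise estimate matches the closed-form definition", {
  expect_equal(estimate_noise(c(1, -2, 3, -4, 5)), 3 / 0.6745)
  expect_error(estimate_noise(numeric(0)), "non-empty")
})

test_that("MAD sigma is calibrated on Gaussian noise and robust to spikes", {
  set.seed(21)
  x <- rnorm(125000, sd = 10)
  expect_lt(abs(estimate_noise(x) - 10) / 10, 0.02)
  # superimpose 5 Hz of -100 uV spikes for 10 s
  w <- 100 * spike_waveform(12500)  # template min is -1, so peak is -100
  xs <- x
  for (t in seq(0.1, 9.9, by = 0.2)) {
    i0 <- round(t * 12500) + 1
    xs[i0:(i0 + 18)] <- xs[i0:(i0 + 18)] + w
  }
  expect_lt(abs(estimate_noise(xs) - 10) / 10, 0.05)
})

test_that("threshold detection recovers noiseless rendered spikes", {
  truth <- c(0.1, 0.45, 0.8)
  x <- make_trace(truth, noise_sigma = 1e-12, amplitude = 50)
  ts <- detect_spikes(x, sigma = 2, sampling_rate = 12500)
  expect_length(ts, 3)
  expect_true(all(abs(ts - truth) < 0.0005))
})

test_that("degenerate and empty detector inputs behave per contract", {
  expect_length(detect_spikes(numeric(0), 1, sampling_rate = 12500), 0)
  expect_length(detect_spikes(rep(0, 1000), 2, sampling_rate = 12500), 0)
  expect_length(detect_spikes(rep(0, 1000), 0, sampling_rate = 12500), 0)
  expect_error(detect_spikes(c(0, -5, 0), 0, sampling_rate = 12500),
               "degenerate")
})

test_that("detector equals the exhaustive-scan oracle on random traces", {
  set.seed(31)
  for (i in 1:20) {
    x <- make_trace(sort(runif(sample(0:8, 1), 0.01, 0.95)),
                    duration = 1)
    sigma <- estimate_noise(x)
    got <- detect_spikes(x, sigma, sampling_rate = 12500)
    want <- oracle_detect(x, sigma, fs = 12500)
    expect_equal(got, want)
  }
})

test_that("raising the threshold multiplier never adds spikes", {
  set.seed(32)
  for (i in 1:10) {
    x <- make_trace(sort(runif(6, 0.01, 0.95)), noise_sigma = 15)
    sigma <- estimate_noise(x)
    counts <- vapply(c(3, 4, 5, 5.5, 7, 9), function(m)
      length(detect_spikes(x, sigma,
                           detector_params(threshold_multiplier = m),
                           sampling_rate = 12500)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detected timestamps are invariant to positive rescaling", {
  set.seed(33)
  x <- make_trace(c(0.2, 0.5, 0.7))
  for (c_scale in c(0.01, 3, 1000)) {
    a <- detect_spikes(x, estimate_noise(x), sampling_rate = 12500)
    b <- detect_spikes(c_scale * x, estimate_noise(c_scale * x),
                       sampling_rate = 12500)
    expect_equal(a, b)
  }
})

test_that("full detection pipeline recovers fixture ground truth", {
  silent <- make_fixture("silent")
  expect_equal(n_spikes(detect_all(silent$recording)), 0L)

  sync <- make_fixture("synchronous_network", duration = 20)
  det <- detect_all(sync$recording)
  expect_length(det$metadata$sigma, 16)
  # sigma estimates the *filtered* noise SD (band-pass removes out-of-band
  # power, so it sits below the raw 10 uV); electrodes must agree closely
  expect_true(all(det$metadata$sigma > 3 & det$metadata$sigma < 10))
  expect_lt(max(det$metadata$sigma) / min(det$metadata$sigma), 1.1)
  true_counts <- lengths(sync$truth$spike_times)
  got_counts <- lengths(det$trains)
  expect_true(all(abs(got_counts - true_counts) <=
                    pmax(1, 0.05 * true_counts)))
})
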