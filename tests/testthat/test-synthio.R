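test_that("background-only spike counts follow Poisson closed form", {
  cfg <- recording_config(duration = 300)
  expected <- 16 * 1.0 * 300
  for (seed in 1:20) {
    p <- sim_params(rng_seed = seed, background_rate = 1.0,
                    burst_rate = 0, participation_prob = 0)
    sim <- simulate_spike_trains(cfg, p)
    total <- n_spikes(sim$trains)
    expect_lt(abs(total - expected), 4 * sqrt(expected))
    # per-electrode counts within 4 sd of their own mean
    per <- lengths(sim$trains$trains)
    expect_true(all(abs(per - 300) < 4 * sqrt(300)))
  }
})

test_that("zero rates give empty trains and no burst windows", {
  cfg <- recording_config(duration = 60)
  p <- sim_params(rng_seed = 3, background_rate = 0, burst_rate = 0,
                  participation_prob = 0)
  sim <- simulate_spike_trains(cfg, p)
  expect_equal(n_spikes(sim$trains), 0L)
  expect_equal(nrow(sim$truth$burst_windows), 0L)
})

test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  cfg <- recording_config(duration = 30)
  p <- sim_params(rng_seed = 99)
  a <- simulate_spike_trains(cfg, p)
  b <- simulate_spike_trains(cfg, p)
  expect_identical(a$truth, b$truth)
  expect_identical(a$trains, b$trains)
})

test_that("ground-truth trains are sorted, in range, sample-deduplicated", {
  cfg <- recording_config(duration = 60)
  for (seed in c(5, 6, 7)) {
    p <- sim_params(rng_seed = seed, background_rate = 3, burst_rate = 8)
    sim <- simulate_spike_trains(cfg, p)
    for (tt in sim$truth$spike_times) {
      expect_false(is.unsorted(tt, strictly = TRUE))
      if (length(tt)) {
        expect_gte(min(tt), 0)
        expect_lte(max(tt), 60)
        expect_false(anyDuplicated(round(tt * 12500)) > 0)
      }
    }
  }
})

test_that("burst windows never overlap and respect the minimum gap", {
  cfg <- recording_config(duration = 300)
  for (seed in 1:10) {
    p <- sim_params(rng_seed = seed, burst_rate = 12)
    w <- simulate_spike_trains(cfg, p)$truth$burst_windows
    if (nrow(w) >= 2) {
      gaps <- w$start[-1] - w$end[-nrow(w)]
      expect_gte(min(gaps), p$min_burst_gap - 1e-9)
    }
    expect_true(all(abs(w$end - w$start - p$burst_duration) < 1e-9))
    expect_true(all(w$start >= 0 & w$end <= 300))
  }
})

test_that("infeasible burst configurations are rejected", {
  expect_error(sim_params(rng_seed = 1, burst_rate = 60,
                          burst_duration = 1),
               "infeasible")
  # feasible density but no room for the hard minimum gap
  p <- sim_params(rng_seed = 1, burst_rate = 30, burst_duration = 1.7)
  expect_error(simulate_spike_trains(recording_config(duration = 60), p),
               "infeasible")
})

test_that("synthesized noise matches the requested sigma", {
  cfg <- recording_config(duration = 10, n_electrodes = 1,
                          layout = c(1L, 1L))
  p <- sim_params(rng_seed = 8, background_rate = 0, burst_rate = 0,
                  participation_prob = 0, noise_sigma = 10)
  sim <- simulate_spike_trains(cfg, p)
  rec <- synthesize_voltage(sim$trains, cfg, p)
  expect_lt(abs(stats::sd(rec$samples[1, ]) - 10) / 10, 0.02)
})

test_that("a spike renders at its sample with the template's peak", {
  cfg <- recording_config(duration = 2, n_electrodes = 1,
                          layout = c(1L, 1L))
  p <- sim_params(rng_seed = 8, noise_sigma = 1e-9, spike_amplitude = 80)
  sts <- spike_train_set(list(1.0), duration = 2)
  rec <- synthesize_voltage(sts, cfg, p)
  ch <- rec$samples[1, ]
  peak0 <- which.min(ch) - 1L  # 0-based
  expect_equal(peak0, 12500L + waveform_peak_offset(12500))
  expect_equal(min(ch), -80, tolerance = 1e-6)
})

test_that("overlapping waveforms sum linearly", {
  cfg <- recording_config(duration = 2, n_electrodes = 1,
                          layout = c(1L, 1L))
  p <- sim_params(rng_seed = 8, noise_sigma = 1e-9, spike_amplitude = 80)
  one <- synthesize_voltage(spike_train_set(list(1.0), duration = 2),
                            cfg, p)
  # two spikes one sample apart: nearly coincident, peaks superpose
  two <- synthesize_voltage(
    spike_train_set(list(c(1.0, 1.0 + 1 / 12500)), duration = 2), cfg, p)
  expect_gt(min(two$samples) / min(one$samples), 1.8)
  expect_lte(min(two$samples) / min(one$samples), 2.0 + 1e-9)
})

test_that("fixtures have the advertised qualitative structure", {
  expect_error(make_fixture("nonsense"), "unknown scenario")

  silent <- make_fixture("silent", voltage = FALSE)
  expect_equal(sum(lengths(silent$truth$spike_times)), 0L)

  sync <- make_fixture("synchronous_network", voltage = FALSE)
  nb <- nrow(sync$truth$burst_windows)
  expected <- 10 * 60 / 60  # burst_rate * duration / 60
  expect_lt(abs(nb - expected), 3 * sqrt(expected) + 1)
  expect_true(all(lengths(sync$truth$participating) >= 1))

  hyper <- make_fixture("hyperexcitable_asynchronous", voltage = FALSE)
  expect_equal(nrow(hyper$truth$burst_windows), 0L)
  rate_sync <- sum(lengths(sync$truth$spike_times)) / 60 / 16
  rate_hyper <- sum(lengths(hyper$truth$spike_times)) / 60 / 16
  expect_gt(rate_hyper, rate_sync)

  tonic <- make_fixture("single_electrode_tonic", voltage = FALSE)
  counts <- lengths(tonic$truth$spike_times)
  expect_equal(sum(counts > 0), 1L)
  expect_equal(unname(counts[1]), length(seq(0.1, 29.95, by = 0.2)))
})
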