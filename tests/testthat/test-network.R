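test_that("ASDR bins by the hand-computed definition", {
  sts <- spike_train_set(list(c(0.05, 0.25), 0.15), duration = 0.4)
  expect_equal(compute_asdr(sts, 0.2)$counts, c(2L, 1L))
  # empty trains over 1 s: five empty bins
  empty <- spike_train_set(list(numeric(0)), duration = 1)
  expect_equal(compute_asdr(empty, 0.2)$counts, rep(0L, 5))
})

test_that("ASDR counts conserve the total spikes in the covered span", {
  set.seed(41)
  for (i in 1:10) {
    sts <- random_train_set(duration = runif(1, 5, 20),
                            rate = runif(1, 0.5, 10))
    w <- sample(c(0.1, 0.2, 0.5), 1)
    asdr <- compute_asdr(sts, w)
    span <- length(asdr$counts) * w
    direct <- sum(unlist(sts$trains) < span)
    expect_equal(sum(asdr$counts), direct)
  }
})

test_that("a flat ASDR yields no synchronized bursts", {
  # two spikes per 0.2 s bin, away from bin edges
  sts <- spike_train_set(list(seq(0.05, 9.95, by = 0.1)), duration = 10)
  asdr <- compute_asdr(sts, 0.2)
  expect_true(all(asdr$counts == asdr$counts[1]))
  sb <- detect_synchronized_bursts(asdr, sts)
  expect_equal(nrow(sb), 0L)
})

test_that("envelope detection recovers simulated burst windows", {
  cfg <- recording_config(duration = 120)
  p <- sim_params(rng_seed = 51, background_rate = 1.5, burst_rate = 10,
                  burst_duration = 0.5, burst_within_rate = 40,
                  participation_prob = 0.9)
  sim <- simulate_spike_trains(cfg, p)
  asdr <- compute_asdr(sim$trains)
  sb <- detect_synchronized_bursts(asdr, sim$trains)
  tw <- sim$truth$burst_windows
  expect_lte(abs(nrow(sb) - nrow(tw)), 1)
  # each detected burst overlaps exactly one true window
  for (i in seq_len(nrow(sb))) {
    n_overlap <- sum(tw$start < sb$end[i] & tw$end > sb$start[i])
    expect_equal(n_overlap, 1L)
  }
  expect_true(all(sb$spike_count > 0))
  expect_true(all(sb$end > sb$start))
})

test_that("asynchronous high firing produces no burst pattern", {
  sync <- make_fixture("synchronous_network", voltage = FALSE)
  hyper <- make_fixture("hyperexcitable_asynchronous", voltage = FALSE)
  sb_sync <- detect_synchronized_bursts(compute_asdr(sync$trains),
                                        sync$trains)
  sb_hyper <- detect_synchronized_bursts(compute_asdr(hyper$trains),
                                         hyper$trains)
  expect_gt(n_spikes(hyper$trains), n_spikes(sync$trains))
  expect_lte(nrow(sb_hyper), 2)
  expect_lt(nrow(sb_hyper), nrow(sb_sync))
})

test_that("increasing the merge separation never adds bursts", {
  cfg <- recording_config(duration = 60)
  for (seed in c(52, 53)) {
    p <- sim_params(rng_seed = seed, burst_rate = 12,
                    burst_duration = 0.4)
    sim <- simulate_spike_trains(cfg, p)
    asdr <- compute_asdr(sim$trains)
    counts <- vapply(c(0.2, 0.4, 0.8, 1.6), function(ms)
      nrow(detect_synchronized_bursts(
        asdr, sim$trains, burst_params(min_separation = ms))),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("mean firing rate follows its definition and contracts", {
  one <- spike_train_set(list(seq(0.5, 99.5, length.out = 100)),
                         duration = 100)
  expect_equal(mean_firing_rate(one), 1.0)

  empty16 <- spike_train_set(rep(list(numeric(0)), 16), duration = 10)
  expect_equal(mean_firing_rate(empty16, active_only = FALSE), 0)
  expect_warning(r <- mean_firing_rate(empty16, active_only = TRUE),
                 "undefined")
  expect_true(is.na(r))

  # Poisson recovery: 16 electrodes at 2 Hz for 300 s
  cfg <- recording_config(duration = 300)
  p <- sim_params(rng_seed = 54, background_rate = 2, burst_rate = 0,
                  participation_prob = 0)
  sim <- simulate_spike_trains(cfg, p)
  se <- sqrt(2 / 300) / 4
  expect_lt(abs(mean_firing_rate(sim$trains) - 2), 3 * se)
})

test_that("active-electrode gating isolates the firing electrode", {
  tonic <- make_fixture("single_electrode_tonic", voltage = FALSE)
  asdr <- compute_asdr(tonic$trains)
  sb <- detect_synchronized_bursts(asdr, tonic$trains)
  expect_equal(length(attr(sb, "active_electrodes")), 1L)
  expect_equal(mean_firing_rate(tonic$trains), 5, tolerance = 0.01)
})

test_that("burst metrics match hand computation and absence rules", {
  bursts <- data.frame(start = c(1, 4), end = c(2, 5),
                       n_electrodes = c(10L, 10L),
                       spike_count = c(100L, 200L),
                       peak_asdr = c(40L, 50L))
  m <- burst_metrics(bursts, duration = 60)
  expect_equal(m$sb_frequency, 2)
  expect_equal(m$mean_sb_duration, 1)
  expect_equal(m$mean_sb_interval, 2)
  expect_equal(m$mean_spikes_per_sb, 150)

  none <- burst_metrics(bursts[0, ], duration = 60)
  expect_equal(none$sb_frequency, 0)
  expect_true(is.na(none$mean_sb_duration))
  expect_true(is.na(none$mean_sb_interval))
  expect_true(is.na(none$mean_spikes_per_sb))

  single <- burst_metrics(bursts[1, ], duration = 60)
  expect_equal(single$sb_frequency, 1)
  expect_true(is.na(single$mean_sb_interval))

  onset <- burst_metrics(bursts, duration = 60, interval_mode = "onset")
  expect_equal(onset$mean_sb_interval, 3)
})

test_that("percent-of-control normalization and its error contract", {
  expect_equal(as.numeric(percent_of_control(c(sb_frequency = 2),
                                             c(sb_frequency = 1))), 200)
  expect_equal(as.numeric(percent_of_control(c(max_asdr = 7),
                                             c(max_asdr = 7))), 100)
  out <- percent_of_control(c(a = 2, b = 3), c(a = 0, b = 1.5))
  expect_true(is.na(out[["a"]]))
  expect_equal(attr(out, "non_normalizable"), "a")
  expect_equal(out[["b"]], 200)
})
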