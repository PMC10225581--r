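#' Biphasic extracellular spike waveform template
#'
#' Negative-leading biphasic shape typical of extracellular action
#' potentials: a negative lobe (40% of the total width) followed by a
#' positive lobe at 30% of the negative amplitude. The template is
#' normalized so its minimum is exactly -1; multiply by the spike
#' amplitude to render a spike.
#'
#' @param sampling_rate Sampling rate, Hz.
#' @param width_ms Total waveform width in milliseconds (default 1.5).
#' @return Numeric vector, the sampled template (min = -1).
#' @export
spike_waveform <- function(sampling_rate, width_ms = 1.5) {
  width <- width_ms / 1000
  n <- max(3L, round(width * sampling_rate))
  t <- (seq_len(n) - 1L) / sampling_rate
  t_neg <- 0.4 * width
  w <- ifelse(t < t_neg,
              -sin(pi * t / t_neg),
              0.3 * sin(pi * (t - t_neg) / (width - t_neg)))
  w / max(abs(w))
}

#' Index offset of the waveform's negative peak
#' @param sampling_rate Sampling rate, Hz.
#' @param width_ms Waveform width, ms.
#' @return 0-based sample offset of the template minimum.
#' @export
waveform_peak_offset <- function(sampling_rate, width_ms = 1.5) {
  which.min(spike_waveform(sampling_rate, width_ms)) - 1L
}

# Draw burst window start times as a renewal process: successive onsets are
# separated by burst_duration + min_gap + Exp(mean = slack), where slack is
# chosen so the mean onset interval equals 60/burst_rate.
draw_burst_windows <- function(duration, params) {
  if (params$burst_rate <= 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  mean_interval <- 60 / params$burst_rate
  slack <- mean_interval - params$burst_duration - params$min_burst_gap
  if (slack <= 0)
    stop("infeasible parameters: mean burst interval (", mean_interval,
         " s) must exceed burst_duration + min_burst_gap (",
         params$burst_duration + params$min_burst_gap, " s)")
  starts <- numeric(0)
  t <- stats::rexp(1, rate = 1 / slack)
  while (t + params$burst_duration <= duration) {
    starts <- c(starts, t)
    t <- t + params$burst_duration + params$min_burst_gap +
      stats::rexp(1, rate = 1 / slack)
  }
  data.frame(start = starts, end = starts + params$burst_duration)
}

# Deduplicate spike times that fall on the same sample: physically one
# event at the electrode.
dedupe_to_sample <- function(times, sampling_rate) {
  if (length(times) < 2L) return(times)
  times <- sort(times)
  times[!duplicated(round(times * sampling_rate))]
}

#' Simulate per-electrode spike trains with known ground truth
#'
#' Background activity is homogeneous Poisson on each electrode at
#' `background_rate`. Network bursts are drawn as a renewal process at
#' `burst_rate` per minute with a hard minimum gap between windows; within
#' each burst every electrode is independently recruited with probability
#' `participation_prob`, and recruited electrodes add Poisson spikes at
#' `burst_within_rate` inside the window. Per-electrode trains are the
#' union of the two processes, sorted, and deduplicated at one-sample
#' resolution. All draws come from one generator seeded with
#' `params$rng_seed`, so identical inputs give identical output.
#'
#' @param config A [recording_config()].
#' @param params A [sim_params()].
#' @return A list with components `trains` (a [spike_train_set()]) and
#'   `truth` (class `ground_truth`: per-electrode true spike times, burst
#'   windows with participating electrode sets, and the parameters used).
#' @examples
#' sim <- simulate_spike_trains(recording_config(duration = 30),
#'                              sim_params(rng_seed = 1, burst_rate = 6))
#' n_spikes(sim$trains)
#' @export
simulate_spike_trains <- function(config, params) {
  stopifnot(inherits(config, "recording_config"),
            inherits(params, "sim_params"))
  set.seed(params$rng_seed)
  duration <- config$duration
  ne <- config$n_electrodes

  windows <- draw_burst_windows(duration, params)
  nb <- nrow(windows)
  participating <- vector("list", nb)

  trains <- vector("list", ne)
  for (e in seq_len(ne)) {
    n_bg <- stats::rpois(1, params$background_rate * duration)
    trains[[e]] <- stats::runif(n_bg, 0, duration)
  }
  if (nb > 0) {
    for (b in seq_len(nb)) {
      recruited <- which(stats::runif(ne) < params$participation_prob)
      participating[[b]] <- as.integer(recruited - 1L)
      for (e in recruited) {
        n_in <- stats::rpois(1, params$burst_within_rate *
                                 params$burst_duration)
        trains[[e]] <- c(trains[[e]],
                         stats::runif(n_in, windows$start[b],
                                      windows$end[b]))
      }
    }
  }
  trains <- lapply(trains, dedupe_to_sample,
                   sampling_rate = config$sampling_rate)

  truth <- structure(
    list(spike_times = trains,
         burst_windows = windows,
         participating = participating,
         params = params, config = config),
    class = "ground_truth")
  sts <- spike_train_set(trains, duration = duration,
                         metadata = list(source = "simulated",
                                         rng_seed = params$rng_seed))
  list(trains = sts, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d electrodes, %d spikes, %d burst windows\n",
              length(x$spike_times), sum(lengths(x$spike_times)),
              nrow(x$burst_windows)))
  invisible(x)
}

#' Render spike trains into a noisy voltage recording
#'
#' Each spike places the biphasic waveform template (scaled so its
#' negative peak equals `-spike_amplitude`) at the spike's sample index;
#' overlapping waveforms sum linearly. White Gaussian noise with standard
#' deviation `noise_sigma` is added to every sample. Output is in
#' physical microvolts (amplifier gain already removed).
#'
#' @param trains A [spike_train_set()]; all spike times must fall inside
#'   the configured duration.
#' @param config A [recording_config()].
#' @param params A [sim_params()] supplying amplitude, noise, and waveform
#'   width.
#' @return A [voltage_recording()].
#' @export
synthesize_voltage <- function(trains, config, params) {
  stopifnot(inherits(trains, "spike_train_set"),
            inherits(config, "recording_config"),
            inherits(params, "sim_params"))
  fs <- config$sampling_rate
  n_samp <- round(config$duration * fs)
  if (any(unlist(trains$trains, use.names = FALSE) >= config$duration))
    stop("all spike times must be < duration")
  w <- params$spike_amplitude * spike_waveform(fs, params$waveform_ms)
  lw <- length(w)
  ne <- config$n_electrodes
  if (length(trains$trains) != ne)
    stop("train set does not match configured electrode count")
  samples <- matrix(stats::rnorm(ne * n_samp, sd = params$noise_sigma),
                    nrow = ne)
  for (e in seq_len(ne)) {
    for (t in trains$trains[[e]]) {
      i0 <- round(t * fs) + 1L
      i1 <- min(i0 + lw - 1L, n_samp)
      samples[e, i0:i1] <- samples[e, i0:i1] + w[seq_len(i1 - i0 + 1L)]
    }
  }
  voltage_recording(samples, sampling_rate = fs,
                    electrode_ids = trains$electrode_ids,
                    layout = config$layout)
}

#' Deterministic benchmark fixtures
#'
#' Fixed-seed synthetic wells imitating the activity phenotypes seen in
#' PUFA-treated cortical cultures on MEAs:
#' \describe{
#'   \item{`synchronous_network`}{A well-connected culture: moderate
#'     background firing with a regular pattern of prominent synchronized
#'     bursts (background 1.5 Hz, 10 bursts/min of 0.5 s at 40 Hz within-
#'     burst rate, 90% electrode participation).}
#'   \item{`hyperexcitable_asynchronous`}{Elevated, desynchronized firing:
#'     background 8 Hz but no network bursts (burst rate and participation
#'     0) — higher total spiking, no clear synchronized-burst pattern.}
#'   \item{`silent`}{No spikes at all; noise only.}
#'   \item{`single_electrode_tonic`}{One electrode firing regular 5 Hz
#'     tonic spikes, all others silent; exercises active-electrode logic.}
#' }
#' All scenarios use 100 uV spikes over 10 uV noise (SNR 10). Rebuilding a
#' scenario with the same arguments is bit-for-bit reproducible.
#'
#' @param scenario_name One of the scenario names above.
#' @param duration Recording length, seconds; each scenario has a default
#'   (60 s; 10 s for `silent`; 30 s for `single_electrode_tonic`).
#' @param seed RNG seed (scenario-specific default).
#' @param voltage If `FALSE`, skip waveform rendering and return `NULL`
#'   for the recording (fast, trains and truth only).
#' @return A list with `recording` (a [voltage_recording()] or `NULL`),
#'   `truth` (ground truth), and `trains` (a [spike_train_set()]).
#' @examples
#' fx <- make_fixture("synchronous_network", duration = 10, voltage = FALSE)
#' nrow(fx$truth$burst_windows)
#' @export
make_fixture <- function(scenario_name, duration = NULL, seed = NULL,
                         voltage = TRUE) {
  scenarios <- list(
    synchronous_network = list(
      duration = 60, seed = 101L,
      params = function(seed) sim_params(
        rng_seed = seed, background_rate = 1.5, burst_rate = 10,
        burst_duration = 0.5, burst_within_rate = 40,
        participation_prob = 0.9)),
    hyperexcitable_asynchronous = list(
      duration = 60, seed = 102L,
      params = function(seed) sim_params(
        rng_seed = seed, background_rate = 8, burst_rate = 0,
        participation_prob = 0)),
    silent = list(
      duration = 10, seed = 103L,
      params = function(seed) sim_params(
        rng_seed = seed, background_rate = 0, burst_rate = 0,
        participation_prob = 0)),
    single_electrode_tonic = list(
      duration = 30, seed = 104L,
      params = function(seed) sim_params(
        rng_seed = seed, background_rate = 0, burst_rate = 0,
        participation_prob = 0))
  )
  if (!scenario_name %in% names(scenarios))
    stop("unknown scenario: '", scenario_name, "' (expected one of ",
         paste(names(scenarios), collapse = ", "), ")")
  sc <- scenarios[[scenario_name]]
  if (is.null(duration)) duration <- sc$duration
  if (is.null(seed)) seed <- sc$seed
  config <- recording_config(duration = duration)
  params <- sc$params(as.integer(seed))

  sim <- simulate_spike_trains(config, params)
  if (scenario_name == "single_electrode_tonic") {
    # regular (clock-like) 5 Hz train on electrode 0, built outside the
    # Poisson machinery; other electrodes stay empty
    tt <- seq(0.1, duration - 0.05, by = 0.2)
    spikes <- c(list(tt), rep(list(numeric(0)), config$n_electrodes - 1L))
    sim$truth$spike_times <- spikes
    sim$trains <- spike_train_set(spikes, duration = duration,
                                  metadata = list(source = "fixture"))
  }
  rec <- if (voltage) synthesize_voltage(sim$trains, config, params) else NULL
  list(recording = rec, truth = sim$truth, trains = sim$trains,
       config = config, params = params, scenario = scenario_name)
}
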