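#' Recording configuration
#'
#' Describes the acquisition geometry and sampling of a single MEA well:
#' a grid of extracellular electrodes sampled simultaneously at a common
#' rate. Defaults correspond to a 24-well CytoView-style plate well
#' (4 x 4 electrode grid) sampled at 12.5 kHz per channel.
#'
#' @param duration Recording length in seconds (> 0).
#' @param n_electrodes Number of electrodes in the well (default 16).
#' @param sampling_rate Samples per second per channel in Hz (default 12500).
#' @param layout Integer vector `c(rows, cols)` of the electrode grid;
#'   must satisfy `rows * cols == n_electrodes`.
#' @return An object of class `recording_config`.
#' @examples
#' recording_config(duration = 60)
#' @export
recording_config <- function(duration, n_electrodes = 16L,
                             sampling_rate = 12500, layout = c(4L, 4L)) {
  stopifnot(is.numeric(duration), length(duration) == 1L, is.finite(duration))
  if (duration <= 0) stop("`duration` must be > 0 seconds")
  n_electrodes <- as.integer(n_electrodes)
  if (n_electrodes < 1L) stop("`n_electrodes` must be >= 1")
  if (sampling_rate <= 0) stop("`sampling_rate` must be > 0 Hz")
  layout <- as.integer(layout)
  if (length(layout) != 2L || prod(layout) != n_electrodes)
    stop("`layout` must be c(rows, cols) with rows * cols == n_electrodes")
  structure(
    list(duration = as.numeric(duration), n_electrodes = n_electrodes,
         sampling_rate = as.numeric(sampling_rate), layout = layout),
    class = "recording_config"
  )
}

#' Simulation parameters for synthetic MEA activity
#'
#' Statistical description of the activity a simulated culture produces:
#' homogeneous Poisson background firing on every electrode, plus network
#' burst events drawn as a renewal process in which a random subset of
#' electrodes is recruited and fires at an elevated rate for the burst
#' duration. Spikes are rendered as biphasic extracellular waveforms on
#' top of additive white Gaussian noise.
#'
#' Burst onsets keep a hard minimum gap of `min_burst_gap` seconds between
#' the end of one burst window and the start of the next (default 0.4 s,
#' twice the downstream burst-merging distance) so that ground-truth bursts
#' are unambiguously separable.
#'
#' @param rng_seed Integer seed; required, every simulated quantity derives
#'   from a single generator seeded with it.
#' @param background_rate Background firing rate per electrode, Hz.
#' @param burst_rate Network burst rate, bursts per minute.
#' @param burst_duration Length of each burst window, seconds.
#' @param burst_within_rate Firing rate of a recruited electrode inside a
#'   burst window, Hz.
#' @param participation_prob Probability that an electrode is recruited
#'   into any given burst, in `[0, 1]`.
#' @param spike_amplitude Absolute amplitude of the negative spike peak, uV.
#' @param noise_sigma Standard deviation of the additive Gaussian noise, uV
#'   (> 0 when voltage is synthesized).
#' @param waveform_ms Total biphasic waveform width in milliseconds.
#' @param min_burst_gap Minimum gap between consecutive burst windows, s.
#' @return An object of class `sim_params`.
#' @examples
#' sim_params(rng_seed = 1, background_rate = 2, burst_rate = 0)
#' @export
sim_params <- function(rng_seed, background_rate = 1.5, burst_rate = 10,
                       burst_duration = 0.5, burst_within_rate = 40,
                       participation_prob = 0.9, spike_amplitude = 100,
                       noise_sigma = 10, waveform_ms = 1.5,
                       min_burst_gap = 0.4) {
  if (missing(rng_seed)) stop("`rng_seed` is required for reproducibility")
  rng_seed <- as.integer(rng_seed)
  rates <- c(background_rate, burst_rate, burst_duration, burst_within_rate)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates and durations must be finite and >= 0")
  if (participation_prob < 0 || participation_prob > 1)
    stop("`participation_prob` must be in [0, 1]")
  if (noise_sigma <= 0) stop("`noise_sigma` must be > 0")
  if (burst_rate > 0 && burst_duration * burst_rate / 60 >= 1)
    stop("infeasible parameters: expected bursts tile the recording ",
         "(burst_duration * burst_rate / 60 must be < 1)")
  structure(
    list(background_rate = background_rate, burst_rate = burst_rate,
         burst_duration = burst_duration,
         burst_within_rate = burst_within_rate,
         participation_prob = participation_prob,
         spike_amplitude = spike_amplitude, noise_sigma = noise_sigma,
         waveform_ms = waveform_ms, min_burst_gap = min_burst_gap,
         rng_seed = rng_seed),
    class = "sim_params"
  )
}

#' Band-pass filter specification
#'
#' Butterworth band-pass used to isolate the spike band from raw
#' extracellular traces. Defaults: 200 Hz high-pass, 3000 Hz low-pass.
#' The stated `order` is the order of the one-way Butterworth design;
#' with `zero_phase = TRUE` the filter is applied forward and backward,
#' doubling the effective order and cancelling phase shift.
#'
#' @param high_pass High-pass cutoff, Hz.
#' @param low_pass Low-pass cutoff, Hz.
#' @param order Butterworth design order (default 2; effective order 4
#'   after bidirectional application).
#' @param zero_phase Apply forward-backward (zero net phase shift)?
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(high_pass = 200, low_pass = 3000, order = 2L,
                        zero_phase = TRUE) {
  if (!(high_pass > 0 && high_pass < low_pass))
    stop("need 0 < high_pass < low_pass")
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be >= 1")
  structure(list(high_pass = high_pass, low_pass = low_pass, order = order,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Spike detector parameters
#'
#' Adaptive threshold detector: a spike is recorded where the filtered
#' signal first crosses below `-threshold_multiplier * sigma`, with sigma
#' the per-electrode MAD-based noise estimate; the timestamp is aligned to
#' the local minimum within the dead-time window after the crossing, and
#' further crossings within the dead time are suppressed. Only
#' negative-going crossings are detected (the extracellular spike polarity).
#'
#' @param threshold_multiplier Threshold in units of sigma (default 5.5).
#' @param dead_time Refractory window after a detected crossing, seconds
#'   (default 1 ms; must be at least one sample period when applied).
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(threshold_multiplier = 5.5, dead_time = 0.001) {
  if (threshold_multiplier <= 0) stop("`threshold_multiplier` must be > 0")
  if (dead_time <= 0) stop("`dead_time` must be > 0 seconds")
  structure(list(threshold_multiplier = threshold_multiplier,
                 dead_time = dead_time),
            class = "detector_params")
}

#' Synchronized-burst detection parameters
#'
#' Parameters of the envelope algorithm on the ASDR histogram: candidate
#' bins exceed the mean by `envelope_threshold_sd` standard deviations,
#' burst edges extend to where counts fall back to the mean, bursts closer
#' than `min_separation` are merged, and a burst is retained only if at
#' least `min_electrode_fraction` of the well's active electrodes (those
#' firing at `active_electrode_min_rate` spikes/min or more over the
#' recording) contribute a spike inside it.
#'
#' @param envelope_threshold_sd Threshold above the mean, in SD units
#'   (default 1.25).
#' @param min_separation Minimum gap between distinct bursts, seconds
#'   (default 0.2, one ASDR bin).
#' @param min_electrode_fraction Minimum fraction of active electrodes
#'   participating (default 0.35).
#' @param active_electrode_min_rate Firing rate (spikes/min) above which an
#'   electrode counts as active (default 5, a common vendor default).
#' @param participation_min_rate_factor An electrode counts as
#'   participating in a burst when it fires at least one spike inside the
#'   window *and* its firing rate within the window is at least this
#'   multiple of its own recording-average rate (default 2, i.e. at least
#'   doubled firing). This is what separates a genuine network burst from
#'   a chance fluctuation of asynchronous activity, which by construction
#'   exceeds a mean + 1.25 SD envelope in roughly a tenth of all bins.
#' @param smoothing Width (in bins) of an optional centered moving average
#'   applied to the ASDR before thresholding; 0 or 1 disables smoothing.
#' @return An object of class `burst_params`.
#' @export
burst_params <- function(envelope_threshold_sd = 1.25, min_separation = 0.2,
                         min_electrode_fraction = 0.35,
                         active_electrode_min_rate = 5,
                         participation_min_rate_factor = 2,
                         smoothing = 0L) {
  if (envelope_threshold_sd < 0) stop("`envelope_threshold_sd` must be >= 0")
  if (min_separation < 0) stop("`min_separation` must be >= 0")
  if (min_electrode_fraction <= 0 || min_electrode_fraction > 1)
    stop("`min_electrode_fraction` must be in (0, 1]")
  if (active_electrode_min_rate < 0)
    stop("`active_electrode_min_rate` must be >= 0")
  if (participation_min_rate_factor < 0)
    stop("`participation_min_rate_factor` must be >= 0")
  smoothing <- as.integer(smoothing)
  structure(list(envelope_threshold_sd = envelope_threshold_sd,
                 min_separation = min_separation,
                 min_electrode_fraction = min_electrode_fraction,
                 active_electrode_min_rate = active_electrode_min_rate,
                 participation_min_rate_factor = participation_min_rate_factor,
                 smoothing = smoothing),
            class = "burst_params")
}
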