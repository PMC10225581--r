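#' Multi-electrode voltage recording
#'
#' Container for a raw or filtered extracellular recording: an
#' electrodes x samples matrix in microvolts plus sampling metadata.
#' Electrode ids are 0-based, row-major over the grid.
#'
#' @param samples Numeric matrix, electrodes in rows, samples in columns, uV.
#' @param sampling_rate Sampling rate in Hz.
#' @param t0 Time of the first sample, seconds (default 0).
#' @param electrode_ids Integer electrode ids (default `0:(nrow - 1)`).
#' @param layout Optional `c(rows, cols)` grid layout.
#' @return An object of class `voltage_recording`.
#' @export
voltage_recording <- function(samples, sampling_rate, t0 = 0,
                              electrode_ids = NULL, layout = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (electrodes x samples)")
  if (!all(is.finite(samples))) stop("voltage samples must all be finite")
  if (sampling_rate <= 0) stop("`sampling_rate` must be > 0")
  if (is.null(electrode_ids)) electrode_ids <- seq_len(nrow(samples)) - 1L
  electrode_ids <- as.integer(electrode_ids)
  if (length(electrode_ids) != nrow(samples))
    stop("one electrode id per matrix row required")
  if (anyDuplicated(electrode_ids)) stop("electrode ids must be unique")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         t0 = as.numeric(t0), electrode_ids = electrode_ids,
         layout = if (is.null(layout)) NULL else as.integer(layout)),
    class = "voltage_recording"
  )
}

#' @export
print.voltage_recording <- function(x, ...) {
  dur <- ncol(x$samples) / x$sampling_rate
  cat(sprintf(
    "<voltage_recording> %d electrodes x %d samples (%.4g s at %g kHz)\n",
    nrow(x$samples), ncol(x$samples), dur, x$sampling_rate / 1000))
  cat(sprintf("  amplitude range: [%.1f, %.1f] uV\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Duration of a recording or spike-train set
#'
#' @param x A `voltage_recording` or `spike_train_set`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(x) {
  if (inherits(x, "voltage_recording")) return(ncol(x$samples) / x$sampling_rate)
  if (inherits(x, "spike_train_set")) return(x$duration)
  stop("no duration defined for this object")
}

#' Per-electrode spike timestamp trains
#'
#' The hinge between spike detection and network analysis: one sorted
#' vector of spike times (seconds) per electrode, plus the recording
#' duration they were observed over. Times must lie in
#' `[t0, t0 + duration]` and be strictly increasing within an electrode.
#'
#' @param trains List of numeric vectors, one per electrode, seconds.
#' @param duration Observation duration in seconds.
#' @param t0 Start time, seconds (default 0).
#' @param electrode_ids Integer ids (default 0-based in list order).
#' @param metadata Optional list (e.g. per-electrode sigma, detector params).
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, duration, t0 = 0, electrode_ids = NULL,
                            metadata = list()) {
  if (!is.list(trains)) stop("`trains` must be a list of numeric vectors")
  if (duration <= 0) stop("`duration` must be > 0")
  if (is.null(electrode_ids)) electrode_ids <- seq_along(trains) - 1L
  electrode_ids <- as.integer(electrode_ids)
  if (length(electrode_ids) != length(trains))
    stop("one electrode id per train required")
  trains <- lapply(trains, as.numeric)
  tol <- 1e-9
  for (i in seq_along(trains)) {
    tt <- trains[[i]]
    if (length(tt) == 0L) next
    if (any(!is.finite(tt))) stop("spike times must be finite")
    if (any(tt < t0 - tol) || any(tt > t0 + duration + tol))
      stop("spike times must lie within [t0, t0 + duration]")
    if (is.unsorted(tt, strictly = TRUE))
      stop("spike times must be strictly increasing within an electrode")
  }
  names(trains) <- as.character(electrode_ids)
  structure(list(trains = trains, duration = as.numeric(duration),
                 t0 = as.numeric(t0), electrode_ids = electrode_ids,
                 metadata = metadata),
            class = "spike_train_set")
}

#' Total spike count of a train set
#' @param trains A `spike_train_set`.
#' @return Integer total number of spikes across electrodes.
#' @export
n_spikes <- function(trains) {
  stopifnot(inherits(trains, "spike_train_set"))
  sum(lengths(trains$trains))
}

#' @export
print.spike_train_set <- function(x, ...) {
  counts <- lengths(x$trains)
  cat(sprintf("<spike_train_set> %d electrodes, %d spikes over %.4g s\n",
              length(x$trains), sum(counts), x$duration))
  cat(sprintf("  spikes/electrode: min %d, median %.1f, max %d\n",
              min(counts), stats::median(counts), max(counts)))
  invisible(x)
}

#' @export
summary.spike_train_set <- function(object, ...) {
  counts <- lengths(object$trains)
  data.frame(electrode = object$electrode_ids,
             n_spikes = as.integer(counts),
             rate_hz = counts / object$duration,
             row.names = NULL)
}

#' Raster plot of a spike-train set
#'
#' @param x A `spike_train_set`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.spike_train_set <- function(x, ...) {
  graphics::plot(NA, xlim = c(x$t0, x$t0 + x$duration),
                 ylim = c(-0.5, length(x$trains) - 0.5),
                 xlab = "time (s)", ylab = "electrode", yaxt = "n", ...)
  graphics::axis(2, at = seq_along(x$trains) - 1L,
                 labels = x$electrode_ids, las = 1)
  for (i in seq_along(x$trains)) {
    tt <- x$trains[[i]]
    if (length(tt))
      graphics::segments(tt, i - 1.35, tt, i - 0.65)
  }
  invisible(x)
}
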