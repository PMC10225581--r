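#' Array-wide spike detection rate (ASDR)
#'
#' Histogram of spikes summed across all electrodes in fixed-width time
#' bins (default 200 ms). Bin `k` counts spikes with
#' `k*w <= t - t0 < (k+1)*w`; a trailing partial bin is dropped.
#'
#' @param trains A [spike_train_set()].
#' @param bin_width Bin width in seconds (default 0.2).
#' @return An object of class `asdr_series` with fields `counts`,
#'   `bin_width`, `t0`.
#' @examples
#' sts <- spike_train_set(list(c(0.05, 0.25), 0.15), duration = 0.4)
#' compute_asdr(sts)$counts  # 2 spikes in [0, 0.2), 1 in [0.2, 0.4)
#' @export
compute_asdr <- function(trains, bin_width = 0.2) {
  stopifnot(inherits(trains, "spike_train_set"))
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  n_bins <- floor(trains$duration / bin_width + 1e-9)
  tt <- unlist(trains$trains, use.names = FALSE)
  if (n_bins < 1L)
    stop("recording shorter than one bin")
  idx <- floor((tt - trains$t0) / bin_width) + 1
  idx <- idx[idx >= 1 & idx <= n_bins]
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(counts = as.integer(counts), bin_width = bin_width,
                 t0 = trains$t0),
            class = "asdr_series")
}

#' @export
print.asdr_series <- function(x, ...) {
  cat(sprintf(
    "<asdr_series> %d bins of %g s; mean %.2f, max %d spikes/bin\n",
    length(x$counts), x$bin_width, mean(x$counts),
    if (length(x$counts)) max(x$counts) else 0L))
  invisible(x)
}

#' @export
plot.asdr_series <- function(x, ...) {
  tt <- x$t0 + (seq_along(x$counts) - 1) * x$bin_width
  graphics::plot(tt, x$counts, type = "h", xlab = "time (s)",
                 ylab = sprintf("spikes per %g s bin", x$bin_width), ...)
  invisible(x)
}

# Electrode ids (0-based) firing at >= min_rate spikes/min over the
# recording.
active_electrodes <- function(trains, min_rate_per_min) {
  rates <- lengths(trains$trains) / (trains$duration / 60)
  trains$electrode_ids[rates >= min_rate_per_min]
}

#' Envelope-based synchronized-burst detection
#'
#' Detects network-wide bursts from the ASDR histogram:
#' \enumerate{
#'   \item candidate bins exceed `mean + envelope_threshold_sd * SD` of
#'     the bin counts;
#'   \item each maximal run of candidate bins is extended left and right
#'     while counts remain above the mean (the envelope edges);
#'   \item bursts separated by less than `min_separation` are merged;
#'   \item a burst is retained only if at least `min_electrode_fraction`
#'     of the well's active electrodes participate in it. An electrode
#'     participates when it fires inside the window at
#'     `participation_min_rate_factor` times its own recording-average
#'     rate or more (with at least one spike) — bursting, not merely
#'     firing. Without the elevated-rate requirement, chance
#'     fluctuations of fully asynchronous activity (which exceed a
#'     mean + 1.25 SD envelope in about 10% of bins whatever the rate)
#'     would be reported as network bursts.
#' }
#' A flat ASDR (SD = 0) yields no bursts.
#'
#' @param asdr An [compute_asdr()] result; must share its start time and
#'   span with `trains`.
#' @param trains The [spike_train_set()] the ASDR was computed from.
#' @param params A [burst_params()].
#' @return A data.frame of class `sb_table` with columns `start`, `end`
#'   (seconds), `n_electrodes` (participating), `spike_count` (all spikes
#'   inside the window), `peak_asdr` (max bin count inside), and a
#'   list-column `electrodes` of participating electrode ids. The ids of
#'   active electrodes are attached as attribute `active_electrodes`.
#' @export
detect_synchronized_bursts <- function(asdr, trains,
                                       params = burst_params()) {
  stopifnot(inherits(asdr, "asdr_series"),
            inherits(trains, "spike_train_set"),
            inherits(params, "burst_params"))
  if (abs(asdr$t0 - trains$t0) > 1e-9)
    stop("ASDR and spike trains have different start times")
  if (length(asdr$counts) * asdr$bin_width > trains$duration + 1e-9)
    stop("ASDR span exceeds the spike-train duration")
  if (params$min_separation < asdr$bin_width)
    stop("`min_separation` must be >= the ASDR bin width")

  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_electrodes = integer(0), spike_count = integer(0),
                      peak_asdr = integer(0))
  empty$electrodes <- list()
  active <- active_electrodes(trains, params$active_electrode_min_rate)
  finish <- function(df) {
    attr(df, "active_electrodes") <- active
    class(df) <- c("sb_table", "data.frame")
    df
  }

  counts <- as.numeric(asdr$counts)
  if (params$smoothing > 1L) {
    k <- rep(1 / params$smoothing, params$smoothing)
    sm <- stats::filter(counts, k, sides = 2)
    counts <- ifelse(is.na(sm), counts, as.numeric(sm))
  }
  nb <- length(counts)
  mu <- mean(counts)
  s <- stats::sd(counts)
  if (nb < 2L || !is.finite(s) || s == 0) return(finish(empty))
  cand <- counts > mu + params$envelope_threshold_sd * s
  if (!any(cand)) return(finish(empty))

  r <- rle(cand)
  ends_all <- cumsum(r$lengths)
  starts_all <- ends_all - r$lengths + 1L
  runs <- cbind(starts_all[r$values], ends_all[r$values])
  # envelope extension: grow each run while neighbouring bins stay above mu
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1]; b <- runs[i, 2]
    while (a > 1L && counts[a - 1L] > mu) a <- a - 1L
    while (b < nb && counts[b + 1L] > mu) b <- b + 1L
    runs[i, ] <- c(a, b)
  }
  # extended runs may now touch or overlap; coalesce, then merge runs whose
  # gap in seconds is below min_separation
  o <- order(runs[, 1])
  runs <- runs[o, , drop = FALSE]
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    gap_bins <- runs[i, 1] - merged[nrow(merged), 2] - 1L
    if (gap_bins * asdr$bin_width < params$min_separation) {
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], runs[i, 2])
    } else {
      merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }

  w <- asdr$bin_width
  start <- asdr$t0 + (merged[, 1] - 1) * w
  end <- asdr$t0 + merged[, 2] * w
  n_active <- length(active)
  keep <- logical(length(start))
  part <- vector("list", length(start))
  spike_count <- integer(length(start))
  peak <- integer(length(start))
  in_active <- trains$electrode_ids %in% active
  mean_rate <- lengths(trains$trains) / trains$duration
  for (i in seq_along(start)) {
    win <- end[i] - start[i]
    fired <- vapply(seq_along(trains$trains), function(e) {
      k <- sum(trains$trains[[e]] >= start[i] &
                 trains$trains[[e]] <= end[i])
      k >= 1L && k / win >=
        params$participation_min_rate_factor * mean_rate[e]
    }, logical(1))
    part[[i]] <- trains$electrode_ids[fired & in_active]
    spike_count[i] <- sum(vapply(trains$trains, function(tt)
      sum(tt >= start[i] & tt <= end[i]), numeric(1)))
    peak[i] <- max(asdr$counts[merged[i, 1]:merged[i, 2]])
    keep[i] <- n_active > 0L &&
      length(part[[i]]) / n_active >= params$min_electrode_fraction
  }
  df <- data.frame(start = start[keep], end = end[keep],
                   n_electrodes = lengths(part)[keep],
                   spike_count = as.integer(spike_count[keep]),
                   peak_asdr = peak[keep])
  df$electrodes <- part[keep]
  finish(df)
}

#' @export
print.sb_table <- function(x, ...) {
  cat(sprintf("<sb_table> %d synchronized bursts (%d active electrodes)\n",
              nrow(x), length(attr(x, "active_electrodes"))))
  if (nrow(x))
    print.data.frame(x[, c("start", "end", "n_electrodes", "spike_count",
                           "peak_asdr")], digits = 4)
  invisible(x)
}

#' Mean firing rate of a well
#'
#' Average of per-electrode firing rates (spike count / duration) over the
#' included electrodes. By default only active electrodes (firing at
#' `active_min_rate` spikes/min or more) are included, so dead electrodes
#' do not dilute the estimate. With no electrode included the rate is
#' undefined: `NA` is returned with a warning, never silently 0.
#'
#' @param trains A [spike_train_set()].
#' @param duration Observation duration, seconds (default from `trains`).
#' @param active_only Restrict to active electrodes? Default `TRUE`.
#' @param active_min_rate Activity cutoff, spikes/min (default 5).
#' @return Mean rate in Hz, or `NA` if no electrode qualifies.
#' @export
mean_firing_rate <- function(trains, duration = trains$duration,
                             active_only = TRUE, active_min_rate = 5) {
  stopifnot(inherits(trains, "spike_train_set"))
  if (duration <= 0) stop("`duration` must be > 0")
  counts <- lengths(trains$trains)
  if (active_only) {
    keep <- counts / (duration / 60) >= active_min_rate
    if (!any(keep)) {
      warning("no active electrodes; mean firing rate undefined")
      return(NA_real_)
    }
    counts <- counts[keep]
  } else if (length(counts) == 0L) {
    stop("no electrodes to average over")
  }
  mean(counts / duration)
}

#' Per-well synchronized-burst summary metrics
#'
#' Summaries of a well's burst activity over a recording: burst frequency
#' (`count / duration * 60`, SBs per minute), mean burst duration, mean
#' inter-burst interval (gap from one burst's end to the next one's
#' start), mean spikes per burst, and the maximum ASDR bin count of the
#' recording. Metrics that are undefined for the observed burst count are
#' reported as `NA`, not 0: all burst shape metrics when no burst was
#' detected, and the interval when fewer than two were.
#'
#' @param bursts An `sb_table` from [detect_synchronized_bursts()],
#'   sorted by start time.
#' @param duration Recording duration, seconds.
#' @param asdr Optional [compute_asdr()] result for `max_asdr` (the
#'   per-recording maximum bin count); `NA` if omitted.
#' @param interval_mode `"gap"` (end to next start, default) or
#'   `"onset"` (start to next start).
#' @return A list with fields `sb_frequency` (per min),
#'   `mean_sb_interval` (s), `mean_sb_duration` (s),
#'   `mean_spikes_per_sb`, `max_asdr`, `n_sb`.
#' @export
burst_metrics <- function(bursts, duration, asdr = NULL,
                          interval_mode = c("gap", "onset")) {
  interval_mode <- match.arg(interval_mode)
  if (duration <= 0) stop("`duration` must be > 0")
  nb <- nrow(bursts)
  if (nb > 1 && is.unsorted(bursts$start)) stop("bursts must be sorted")
  max_asdr <- if (is.null(asdr)) NA_real_ else {
    if (length(asdr$counts)) max(asdr$counts) else NA_real_
  }
  if (nb == 0L) {
    return(list(sb_frequency = 0, mean_sb_interval = NA_real_,
                mean_sb_duration = NA_real_,
                mean_spikes_per_sb = NA_real_,
                max_asdr = max_asdr, n_sb = 0L))
  }
  intervals <- if (nb >= 2L) {
    if (interval_mode == "gap")
      bursts$start[-1] - bursts$end[-nb]
    else diff(bursts$start)
  } else NA_real_
  list(sb_frequency = nb / duration * 60,
       mean_sb_interval = mean(intervals),
       mean_sb_duration = mean(bursts$end - bursts$start),
       mean_spikes_per_sb = mean(bursts$spike_count),
       max_asdr = max_asdr, n_sb = nb)
}

#' All well-level metrics in one call
#'
#' Convenience wrapper running ASDR construction, synchronized-burst
#' detection and metric computation on a spike-train set.
#'
#' @param trains A [spike_train_set()].
#' @param bin_width ASDR bin width, seconds.
#' @param params A [burst_params()].
#' @param interval_mode Passed to [burst_metrics()].
#' @return An object of class `well_metrics`: the [burst_metrics()]
#'   fields plus `mean_firing_rate` (Hz over active electrodes, `NA` if
#'   none) and `n_active_electrodes`, with the burst table and ASDR
#'   attached as attributes `bursts` and `asdr`.
#' @export
well_metrics <- function(trains, bin_width = 0.2, params = burst_params(),
                         interval_mode = "gap") {
  asdr <- compute_asdr(trains, bin_width)
  bursts <- detect_synchronized_bursts(asdr, trains, params)
  m <- burst_metrics(bursts, trains$duration, asdr,
                     interval_mode = interval_mode)
  active <- attr(bursts, "active_electrodes")
  m$mean_firing_rate <- if (length(active) == 0L) NA_real_ else
    suppressWarnings(mean_firing_rate(
      trains, active_only = TRUE,
      active_min_rate = params$active_electrode_min_rate))
  m$n_active_electrodes <- length(active)
  structure(m, class = "well_metrics", bursts = bursts, asdr = asdr)
}

#' @export
print.well_metrics <- function(x, ...) {
  fmt <- function(v, unit = "") {
    if (is.na(v)) "NA" else sprintf("%.4g%s", v, unit)
  }
  cat("<well_metrics>\n")
  cat("  mean firing rate:   ", fmt(x$mean_firing_rate, " Hz"), "\n")
  cat("  active electrodes:  ", x$n_active_electrodes, "\n")
  cat("  SB frequency:       ", fmt(x$sb_frequency, " /min"),
      sprintf(" (%d bursts)", x$n_sb), "\n")
  cat("  mean SB duration:   ", fmt(x$mean_sb_duration, " s"), "\n")
  cat("  mean SB interval:   ", fmt(x$mean_sb_interval, " s"), "\n")
  cat("  mean spikes per SB: ", fmt(x$mean_spikes_per_sb), "\n")
  cat("  max ASDR:           ", fmt(x$max_asdr, " spikes/bin"), "\n")
  invisible(x)
}

#' Normalize metrics to a control condition
#'
#' Expresses metric values as percentages of a control value
#' (`100 * value / control`). A metric whose control value is missing,
#' zero or negative cannot be normalized; it is returned as `NA` and
#' listed in the `non_normalizable` attribute.
#'
#' @param metrics Named numeric vector (or `well_metrics`) of values.
#' @param control_metrics Named numeric vector (or `well_metrics`) of
#'   control values; matched by name.
#' @return Named numeric vector of percentages with attribute
#'   `non_normalizable` naming the flagged fields.
#' @examples
#' percent_of_control(c(sb_frequency = 2), c(sb_frequency = 1))  # 200
#' @export
percent_of_control <- function(metrics, control_metrics) {
  as_vec <- function(m) {
    if (inherits(m, "well_metrics"))
      m <- unclass(m)[c("mean_firing_rate", "sb_frequency",
                        "mean_sb_interval", "mean_sb_duration",
                        "mean_spikes_per_sb", "max_asdr")]
    unlist(m)
  }
  v <- as_vec(metrics)
  ctrl <- as_vec(control_metrics)
  common <- intersect(names(v), names(ctrl))
  if (length(common) == 0L) stop("no common metric names to normalize")
  out <- rep(NA_real_, length(common))
  names(out) <- common
  bad <- character(0)
  for (nm in common) {
    if (is.na(ctrl[[nm]]) || ctrl[[nm]] <= 0) {
      bad <- c(bad, nm)
    } else if (!is.na(v[[nm]])) {
      out[[nm]] <- 100 * v[[nm]] / ctrl[[nm]]
    }
  }
  attr(out, "non_normalizable") <- bad
  out
}
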