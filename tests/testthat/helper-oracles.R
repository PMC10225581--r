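# Independent oracles and small builders shared across tests.

# Exhaustive sample-by-sample threshold-crossing detector: walk the trace,
# record a spike at each first crossing below -mult*sigma not within the
# dead time of the previously accepted crossing, timestamp at the local
# minimum inside the dead-time window.
oracle_detect <- function(x, sigma, mult = 5.5, dead_time = 0.001, fs,
                          t0 = 0) {
  thr <- -mult * sigma
  dead_n <- round(dead_time * fs)
  n <- length(x)
  times <- numeric(0)
  last <- -Inf
  prev_below <- FALSE
  for (i in seq_len(n)) {
    below <- x[i] < thr
    if (below && !prev_below && i >= last + dead_n) {
      j <- min(i + dead_n - 1L, n)
      k <- i
      for (m in i:j) if (x[m] < x[k]) k <- m
      times <- c(times, t0 + (k - 1L) / fs)
      last <- i
    }
    prev_below <- below
  }
  times
}

# Textbook one-way ANOVA from between/within sums of squares.
oracle_anova <- function(groups) {
  N <- sum(lengths(groups))
  k <- length(groups)
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# Greedy one-to-one matching of detected to true spike times within a
# tolerance; returns matched count and unmatched detections.
match_spikes <- function(detected, truth, tol) {
  used <- rep(FALSE, length(detected))
  matched <- 0L
  for (t in truth) {
    j <- which(!used & abs(detected - t) <= tol)
    if (length(j)) {
      used[j[1]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(matched = matched, false_pos = sum(!used))
}

# A short noisy trace with spikes rendered at known times.
make_trace <- function(spike_times, fs = 12500, duration = 1,
                       amplitude = 100, noise_sigma = 10) {
  n <- round(duration * fs)
  x <- stats::rnorm(n, sd = noise_sigma)
  w <- amplitude * spike_waveform(fs)
  for (t in spike_times) {
    i0 <- round(t * fs) + 1L
    i1 <- min(i0 + length(w) - 1L, n)
    x[i0:i1] <- x[i0:i1] + w[seq_len(i1 - i0 + 1L)]
  }
  x
}

random_train_set <- function(n_electrodes = 8, duration = 30,
                             rate = 3) {
  trains <- lapply(seq_len(n_electrodes), function(e) {
    n <- stats::rpois(1, rate * duration)
    sort(stats::runif(n, 0, duration))
  })
  spike_train_set(trains, duration = duration)
}
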