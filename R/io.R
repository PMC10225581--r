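#' Write spike trains to delimited text
#'
#' Long-format CSV with columns `electrode` (integer id) and `time_s`
#' (full double precision), one row per spike, plus a JSON sidecar
#' (`<path>.json`) holding duration, start time, electrode ids, and any
#' metadata (per-electrode sigma, detector parameters).
#'
#' @param trains A [spike_train_set()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spike_csv <- function(trains, path) {
  stopifnot(inherits(trains, "spike_train_set"))
  df <- data.frame(
    electrode = rep(trains$electrode_ids, lengths(trains$trains)),
    time_s = unlist(trains$trains, use.names = FALSE))
  data.table::fwrite(df, path)
  meta <- list(duration = trains$duration, t0 = trains$t0,
               electrode_ids = trains$electrode_ids,
               metadata = trains$metadata["sigma"])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read spike trains from delimited text
#'
#' Reads a spike CSV written by [write_spike_csv()] or exported from
#' other MEA software (columns `electrode`, `time_s`). Unsorted times are
#' accepted and sorted with a warning; negative times, non-numeric rows
#' and missing columns are rejected. If the JSON sidecar is absent,
#' `duration` must be given (electrodes are then taken from the data).
#'
#' @param path CSV path.
#' @param duration Recording duration (s), required without a sidecar.
#' @param n_electrodes Optionally force the electrode count (ids
#'   `0:(n_electrodes-1)`), so silent electrodes are represented.
#' @return A [spike_train_set()].
#' @export
read_spike_csv <- function(path, duration = NULL, n_electrodes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  req <- c("electrode", "time_s")
  if (!all(req %in% names(df)))
    stop("spike CSV must have columns 'electrode' and 'time_s'")
  if (nrow(df) > 0 &&
      (!is.numeric(df$time_s) || !is.numeric(df$electrode) ||
       any(!is.finite(df$time_s)) || any(!is.finite(df$electrode))))
    stop("malformed spike CSV: non-numeric electrode or time values")
  if (nrow(df) > 0 && any(df$time_s < 0))
    stop("spike CSV contains negative times")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  ids <- if (!is.null(n_electrodes)) {
    seq_len(n_electrodes) - 1L
  } else if (!is.null(meta)) {
    as.integer(unlist(meta$electrode_ids))
  } else sort(unique(as.integer(df$electrode)))
  if (nrow(df) > 0 && !all(as.integer(df$electrode) %in% ids))
    stop("spike CSV contains electrode ids outside the declared set")
  if (is.null(duration)) {
    if (is.null(meta)) stop("`duration` required when no sidecar exists")
    duration <- as.numeric(meta$duration)
  }
  t0 <- if (!is.null(meta)) as.numeric(meta$t0) else 0
  trains <- lapply(ids, function(id) {
    tt <- df$time_s[df$electrode == id]
    if (is.unsorted(tt)) {
      warning("unsorted spike times for electrode ", id,
              "; sorting on load")
      tt <- sort(tt)
    }
    unique(tt)
  })
  spike_train_set(trains, duration = duration, t0 = t0,
                  electrode_ids = ids,
                  metadata = list(source = path))
}

#' Write a voltage recording to a self-describing text container
#'
#' One-file container: the first line is a JSON header (prefixed
#' `#MEAVOLT1 `) carrying sampling rate, start time, electrode ids and
#' layout; the rest is a CSV matrix, one column per electrode, one row
#' per sample, at single-precision (7 significant digits).
#'
#' @param rec A [voltage_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_voltage <- function(rec, path) {
  stopifnot(inherits(rec, "voltage_recording"))
  meta <- list(format = "MEAVOLT1", sampling_rate = rec$sampling_rate,
               t0 = rec$t0, electrode_ids = rec$electrode_ids,
               layout = rec$layout, units = "uV")
  header <- paste0("#MEAVOLT1 ",
                   jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  writeLines(header, path)
  m <- signif(t(rec$samples), 7)
  colnames(m) <- paste0("e", rec$electrode_ids)
  data.table::fwrite(as.data.frame(m), path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a voltage recording from the text container
#'
#' @param path Path written by [write_voltage()].
#' @return A [voltage_recording()].
#' @export
read_voltage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#MEAVOLT1 "))
    stop("not a MEAVOLT1 container: ", path)
  meta <- jsonlite::fromJSON(sub("^#MEAVOLT1 ", "", header))
  df <- data.table::fread(path, skip = 1L, data.table = FALSE)
  samples <- t(as.matrix(df))
  ids <- as.integer(meta$electrode_ids)
  if (nrow(samples) != length(ids))
    stop("container column count does not match declared electrode ids")
  if (!all(is.finite(samples))) stop("container holds non-finite samples")
  rownames(samples) <- NULL
  voltage_recording(samples, sampling_rate = as.numeric(meta$sampling_rate),
                    t0 = as.numeric(meta$t0), electrode_ids = ids,
                    layout = if (length(meta$layout))
                      as.integer(meta$layout) else NULL)
}
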