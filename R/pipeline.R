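#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain. Defaults mirror the
#' standard acquisition/analysis settings: 200-3000 Hz band-pass,
#' -5.5 x sigma detection, 200 ms ASDR bins, 1.25 SD envelope threshold
#' with 200 ms minimum separation and 35% electrode participation, and
#' ROUT at Q = 10% before group comparison.
#'
#' @param filter A [filter_spec()].
#' @param detector A [detector_params()].
#' @param bursts A [burst_params()].
#' @param bin_width ASDR bin width, seconds.
#' @param rout_q ROUT maximum desired FDR applied per group and metric
#'   before ANOVA; `NULL` disables outlier removal.
#' @param seed Integer seed recorded in the manifest (the analysis chain
#'   itself is deterministic; the seed matters when inputs are simulated).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_spec(),
                            detector = detector_params(),
                            bursts = burst_params(), bin_width = 0.2,
                            rout_q = 0.10, seed = 1L) {
  stopifnot(inherits(filter, "filter_spec"),
            inherits(detector, "detector_params"),
            inherits(bursts, "burst_params"))
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  if (bursts$min_separation < bin_width)
    stop("burst `min_separation` must be >= `bin_width`")
  if (!is.null(rout_q) && (rout_q <= 0 || rout_q >= 1))
    stop("`rout_q` must be in (0, 1) or NULL")
  structure(list(filter = filter, detector = detector, bursts = bursts,
                 bin_width = bin_width, rout_q = rout_q,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trip-stable serialization of a [pipeline_config()]; unknown keys
#' are rejected so a typo cannot silently fall back to a default.
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("filter", "detector", "bursts", "bin_width", "rout_q", "seed")
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  build <- function(ctor, args) do.call(ctor, if (is.null(args)) list() else args)
  pipeline_config(
    filter = build(filter_spec, y$filter),
    detector = build(detector_params, y$detector),
    bursts = build(burst_params, y$bursts),
    bin_width = if (is.null(y$bin_width)) 0.2 else y$bin_width,
    rout_q = if (is.null(y$rout_q)) 0.10 else y$rout_q,
    seed = if (is.null(y$seed)) 1L else y$seed)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(y, path)
  invisible(path)
}

config_manifest <- function(config) {
  list(package = "meaburst",
       version = as.character(utils::packageVersion("meaburst")),
       parameters = lapply(unclass(config),
                           function(x) if (is.list(x)) unclass(x) else x))
}

# Normalize one well input (recording / trains / file path) to a voltage
# recording or spike-train set.
load_well <- function(x) {
  if (inherits(x, c("spike_train_set", "voltage_recording"))) return(x)
  if (is.character(x) && length(x) == 1L) {
    first <- readLines(x, n = 1L)
    if (startsWith(first, "#MEAVOLT1 ")) return(read_voltage(x))
    return(read_spike_csv(x))
  }
  stop("well inputs must be voltage recordings, spike-train sets, ",
       "or file paths")
}

#' Run the full analysis pipeline over grouped wells
#'
#' Composition of the whole chain: per well, voltage inputs are filtered
#' and spike-detected, ASDR and synchronized bursts computed, and
#' well-level metrics derived; across wells, each metric is compared
#' between conditions with ROUT outlier removal (per group) followed by
#' one-way ANOVA, and normalized to a control condition when one is
#' named. Deterministic: the same configuration and inputs always give
#' identical outputs.
#'
#' @param inputs Named list: one entry per condition label, each a list
#'   of wells (a [voltage_recording()], [spike_train_set()], or path to a
#'   voltage container / spike CSV). All wells must share one sampling
#'   rate.
#' @param config A [pipeline_config()].
#' @param control Optional control condition label for
#'   percent-of-control normalization.
#' @param output_dir Optional directory; when given, writes
#'   `well_metrics.csv`, `bursts.csv`, `comparison.json`, and
#'   `manifest.json`.
#' @return An object of class `mea_pipeline_result`: `metrics`
#'   (data.frame, one row per well), `bursts` (data.frame over all
#'   wells), `comparison` (per-metric ANOVA summaries),
#'   `percent_of_control` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         control = NULL, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.list(inputs) || is.null(names(inputs)) ||
      any(names(inputs) == ""))
    stop("`inputs` must be a named list (condition -> list of wells)")
  if (!is.null(control) && !control %in% names(inputs))
    stop("unknown control condition label: ", control)

  metric_names <- c("mean_firing_rate", "sb_frequency",
                    "mean_sb_interval", "mean_sb_duration",
                    "mean_spikes_per_sb", "max_asdr")
  rows <- list()
  burst_rows <- list()
  fs_seen <- numeric(0)
  for (cond in names(inputs)) {
    wells <- inputs[[cond]]
    if (!is.list(wells)) wells <- list(wells)
    for (wi in seq_along(wells)) {
      well <- load_well(wells[[wi]])
      if (inherits(well, "voltage_recording")) {
        fs_seen <- unique(c(fs_seen, well$sampling_rate))
        if (length(fs_seen) > 1L)
          stop("mixed sampling rates across wells: ",
               paste(fs_seen, collapse = ", "), " Hz")
        trains <- detect_all(well, config$filter, config$detector)
      } else {
        trains <- well
      }
      wm <- well_metrics(trains, bin_width = config$bin_width,
                         params = config$bursts)
      row <- data.frame(condition = cond, well = wi,
                        n_spikes = n_spikes(trains),
                        n_active_electrodes = wm$n_active_electrodes,
                        n_sb = wm$n_sb)
      for (m in metric_names) row[[m]] <- wm[[m]]
      rows[[length(rows) + 1L]] <- row
      bt <- attr(wm, "bursts")
      if (nrow(bt)) {
        burst_rows[[length(burst_rows) + 1L]] <- data.frame(
          condition = cond, well = wi,
          bt[, c("start", "end", "n_electrodes", "spike_count",
                 "peak_asdr")])
      }
    }
  }
  metrics <- do.call(rbind, rows)
  bursts <- if (length(burst_rows)) do.call(rbind, burst_rows) else
    data.frame(condition = character(0), well = integer(0),
               start = numeric(0), end = numeric(0),
               n_electrodes = integer(0), spike_count = integer(0),
               peak_asdr = integer(0))

  comparison <- list()
  for (m in metric_names) {
    groups <- split(metrics[[m]], metrics$condition)
    groups <- lapply(groups, function(v) v[!is.na(v)])
    if (!is.null(config$rout_q)) {
      groups <- lapply(groups, function(v)
        if (length(v) >= 3L) v[rout_outliers(v, config$rout_q)] else v)
    }
    groups <- groups[lengths(groups) >= 2L]
    comparison[[m]] <- if (length(groups) >= 2L) {
      res <- tryCatch(one_way_anova(groups), error = function(e) NULL)
      if (is.null(res)) list(note = "degenerate or unavailable") else
        list(F = res$F, df = unname(res$df), p = res$p,
             means = as.list(res$means), sems = as.list(res$sems),
             n = as.list(as.integer(res$n)))
    } else list(note = "not enough wells per condition")
  }

  poc <- NULL
  if (!is.null(control)) {
    cond_means <- lapply(split(metrics[metric_names], metrics$condition),
                         function(d) colMeans(d, na.rm = TRUE))
    ctrl <- cond_means[[control]]
    poc <- lapply(cond_means, percent_of_control, control_metrics = ctrl)
  }

  manifest <- config_manifest(config)
  manifest$conditions <- lapply(inputs, length)
  manifest$control <- control

  result <- structure(
    list(metrics = metrics, bursts = bursts, comparison = comparison,
         percent_of_control = poc, manifest = manifest),
    class = "mea_pipeline_result")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(metrics, file.path(output_dir, "well_metrics.csv"))
    data.table::fwrite(bursts, file.path(output_dir, "bursts.csv"))
    jsonlite::write_json(comparison,
                         file.path(output_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.mea_pipeline_result <- function(x, ...) {
  cat(sprintf("<mea_pipeline_result> %d wells in %d conditions, %d SBs\n",
              nrow(x$metrics), length(unique(x$metrics$condition)),
              nrow(x$bursts)))
  print(x$metrics, digits = 4)
  invisible(x)
}
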