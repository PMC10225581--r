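#' Robust outlier removal (ROUT) for a single group
#'
#' One-sample reduction of the robust-regression-and-outlier-removal
#' procedure used for grouped endpoint data: the robust location is the
#' median; the robust scale (RSDR) is the 68.27th percentile of the
#' absolute residuals, inflated by `n / (n - 1)` for the one fitted
#' parameter; each point's two-sided p-value comes from the t
#' distribution of `|residual| / RSDR` on `n - 1` degrees of freedom; and
#' points are flagged by a Benjamini-Hochberg step-up at the maximum
#' desired false-discovery rate `Q`. With all residuals zero nothing is
#' removed; with RSDR zero but some residuals nonzero those points are
#' infinitely extreme and are removed.
#'
#' @param values Numeric vector of at least 3 observations.
#' @param Q Maximum desired FDR for flagged outliers (default 0.10).
#' @return Logical mask, `TRUE` for retained values, with the flagged
#'   indices in attribute `outliers`.
#' @examples
#' rout_outliers(c(1.0, 1.1, 0.9, 1.05, 50))  # flags the 50
#' @export
rout_outliers <- function(values, Q = 0.10) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("ROUT needs at least 3 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (Q <= 0 || Q >= 1) stop("`Q` must be in (0, 1)")
  resid <- values - stats::median(values)
  ares <- abs(resid)
  rsdr <- stats::quantile(ares, 0.6827, names = FALSE) * n / (n - 1)
  if (rsdr == 0) {
    keep <- ares == 0
  } else {
    p <- 2 * stats::pt(ares / rsdr, df = n - 1, lower.tail = FALSE)
    keep <- stats::p.adjust(p, method = "BH") > Q
  }
  attr(keep, "outliers") <- which(!keep)
  keep
}

#' One-way ANOVA with per-group means and SEMs
#'
#' Standard between/within sum-of-squares F test across two or more
#' groups, reporting the group means and standard errors of the mean
#' alongside the omnibus statistic. The model fit is delegated to
#' [stats::lm()]/[stats::anova()].
#'
#' @param groups Named list of numeric vectors, one per group, each with
#'   at least 2 values (after any outlier removal).
#' @return An object of class `mea_anova`: `F`, `df` (between, within),
#'   `p`, `means`, `sems`, `n`, and the underlying ANOVA `table`.
#' @examples
#' one_way_anova(list(a = c(3, 4, 5), b = c(6, 7, 8)))
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("each group needs at least 2 values")
  if (all(vapply(groups, stats::var, numeric(1)) == 0))
    stop("degenerate ANOVA: zero within-group variance in every group")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups)))
  tab <- stats::anova(stats::lm(value ~ group, data = df))
  means <- vapply(groups, mean, numeric(1))
  sems <- vapply(groups, function(x) stats::sd(x) / sqrt(length(x)),
                 numeric(1))
  structure(
    list(F = tab["group", "F value"],
         df = c(between = tab["group", "Df"],
                within = tab["Residuals", "Df"]),
         p = tab["group", "Pr(>F)"],
         means = means, sems = sems, n = sizes, table = tab),
    class = "mea_anova")
}

#' @export
print.mea_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[["between"]], x$df[["within"]], x$F, x$p))
  print(data.frame(group = names(x$means), n = as.integer(x$n),
                   mean = x$means, sem = x$sems, row.names = NULL),
        digits = 4)
  invisible(x)
}

#' A qPCR measurement (technical triplicates)
#'
#' Threshold-cycle (Ct) values for one sample: the target gene and the
#' reference gene (e.g. beta-actin), each as a vector of technical
#' replicates. Replicates are averaged on the Ct scale.
#'
#' @param sample Sample identifier.
#' @param condition Condition label.
#' @param ct_target Numeric Ct replicates for the target gene.
#' @param ct_reference Numeric Ct replicates for the reference gene.
#' @return An object of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(sample, condition, ct_target, ct_reference) {
  for (ct in list(ct_target, ct_reference)) {
    if (length(ct) == 0L || any(!is.finite(ct)) || any(ct <= 0))
      stop("Ct values must be positive, finite, and non-empty")
  }
  structure(list(sample = sample, condition = condition,
                 ct_target = as.numeric(ct_target),
                 ct_reference = as.numeric(ct_reference)),
            class = "qpcr_measurement")
}

#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target gene in a treated sample relative to a control
#' sample, both normalized to a reference gene:
#' `dCt = mean(Ct_target) - mean(Ct_reference)` per sample,
#' `ddCt = dCt_treated - dCt_control`, fold change `2^-ddCt`.
#'
#' @param treated,control [qpcr_measurement()] objects.
#' @return A list with `fold_change`, `ddct`, `dct_treated`,
#'   `dct_control`.
#' @examples
#' tr <- qpcr_measurement("s1", "treated", c(20, 20, 20), c(18, 18, 18))
#' ct <- qpcr_measurement("s2", "control", c(22, 22, 22), c(18, 18, 18))
#' delta_delta_ct(tr, ct)$fold_change  # 4
#' @export
delta_delta_ct <- function(treated, control) {
  stopifnot(inherits(treated, "qpcr_measurement"),
            inherits(control, "qpcr_measurement"))
  dct_t <- mean(treated$ct_target) - mean(treated$ct_reference)
  dct_c <- mean(control$ct_target) - mean(control$ct_reference)
  ddct <- dct_t - dct_c
  list(fold_change = 2^(-ddct), ddct = ddct,
       dct_treated = dct_t, dct_control = dct_c)
}
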