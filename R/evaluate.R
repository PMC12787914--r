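#' Per-object error records for one device
#'
#' One row per reference object with the device's estimate and the signed
#' error `estimate - reference` (positive = overestimate). Undetected
#' objects carry no estimate and no error.
#'
#' @param ref A `reference_table` from [read_reference_table()].
#' @param device Device label; must match a `<device>_detected` column.
#' @return Data frame with `id`, `reference`, `detected`, `estimate`,
#'   `error`.
#' @export
error_table <- function(ref, device) {
  stopifnot(inherits(ref, "reference_table"))
  devices <- attr(ref, "devices")
  if (!device %in% devices)
    stop(sprintf("unknown device '%s'; table has: %s", device,
                 paste(devices, collapse = ", ")))
  est <- ref[[paste0(device, "_est")]]
  det <- ref[[paste0(device, "_detected")]]
  data.frame(id = ref$id, reference = ref$reference, detected = det,
             estimate = est, error = est - ref$reference)
}

#' Error summary statistics
#'
#' Root-mean-square error `sqrt(sum(e_i^2) / n)` and mean signed error
#' (bias), plus their relative forms as a percentage of the mean reference
#' value, and the squared Pearson correlation of reference vs estimate.
#'
#' @param errors Numeric vector of signed errors (estimate - reference);
#'   `NA`s (undetected objects) are dropped.
#' @return The statistic as a single number.
#' @export
rmse <- function(errors) {
  e <- errors[!is.na(errors)]
  if (length(e) == 0L) stop("no detected observations: RMSE undefined")
  sqrt(mean(e^2))
}

#' @rdname rmse
#' @export
bias <- function(errors) {
  e <- errors[!is.na(errors)]
  if (length(e) == 0L) stop("no detected observations: bias undefined")
  mean(e)
}

#' @rdname rmse
#' @param refs Reference values matching `errors` (for the relative forms)
#'   or `ests` (for `r2`).
#' @export
rrmse <- function(errors, refs) 100 * rmse(errors) / mean(refs, na.rm = TRUE)

#' @rdname rmse
#' @export
rbias <- function(errors, refs) 100 * bias(errors) / mean(refs, na.rm = TRUE)

#' @rdname rmse
#' @param ests Estimates matching `refs`.
#' @export
r2 <- function(refs, ests) {
  ok <- !is.na(refs) & !is.na(ests)
  if (sum(ok) < 2L) stop("need at least 2 paired observations for R^2")
  stats::cor(refs[ok], ests[ok])^2
}

#' Target detection rate
#'
#' Percentage of reference objects the device detected. Undetected objects
#' are excluded from RMSE/bias but counted here, separating measurement
#' performance from detection capability.
#'
#' @param ref A `reference_table`.
#' @param device Device label.
#' @return Detection rate in percent (full precision; round for display).
#' @export
detection_rate <- function(ref, device) {
  et <- error_table(ref, device)
  100 * sum(et$detected) / nrow(et)
}

#' Mean, variability and range of a sample
#'
#' The variability is the population (divisor-n) standard deviation by
#' default; set `sample = TRUE` for the divisor-(n-1) form.
#'
#' @param values Non-empty numeric vector.
#' @param sample Use the sample SD instead of the population SD.
#' @return List with `mean`, `sd`, `min`, `max`.
#' @export
summary_stats <- function(values, sample = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("`values` is empty")
  n <- length(values)
  v <- if (n == 1L) 0 else stats::var(values) * (if (sample) 1 else (n - 1) / n)
  list(mean = mean(values), sd = sqrt(v), min = min(values), max = max(values))
}

#' Paired t-test of estimates against reference values
#'
#' Classical paired t with n - 1 degrees of freedom, two-sided, with a 95%
#' confidence interval for the mean difference (estimate - reference).
#'
#' @param est,ref Equal-length numeric vectors (pairs with `NA`s dropped);
#'   at least 2 complete pairs with nonzero difference variance.
#' @return List with `mean_diff`, `ci` (95%), `t`, `df`, `p`, `n`.
#' @export
paired_t <- function(est, ref) {
  if (length(est) != length(ref)) stop("`est` and `ref` lengths differ")
  ok <- !is.na(est) & !is.na(ref)
  d <- est[ok] - ref[ok]
  if (length(d) < 2L) stop("need at least 2 complete pairs")
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences: t statistic undefined")
  ht <- stats::t.test(est[ok], ref[ok], paired = TRUE, conf.level = 0.95)
  ci <- as.numeric(ht$conf.int)
  list(mean_diff = unname(ht$estimate), ci = ci,
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, n = length(d))
}

#' One-way ANOVA across devices with Tukey HSD post hoc test
#'
#' Tests whether device error distributions differ (F test on between- vs
#' within-device variance); when the ANOVA is significant at `alpha`, runs
#' Tukey's Honest Significant Difference test for the pairwise contrasts.
#'
#' @param error_groups Named list of numeric error vectors, one per device;
#'   at least 2 groups with at least 2 observations each.
#' @param alpha Significance gate for running the post hoc test, default
#'   0.05.
#' @return An object of class `device_comparison`: list with `anova`
#'   (`F`, `df`, `p`), `tukey` (data frame of pairwise differences,
#'   confidence bounds and adjusted p-values; `NULL` when the ANOVA is not
#'   significant) and `alpha`.
#' @export
anova_tukey <- function(error_groups, alpha = 0.05) {
  if (!is.list(error_groups) || length(error_groups) < 2L)
    stop("need at least 2 device groups")
  error_groups <- lapply(error_groups, function(e) e[!is.na(e)])
  if (any(lengths(error_groups) < 2L))
    stop("each device group needs at least 2 observations")
  if (is.null(names(error_groups)))
    names(error_groups) <- paste0("group", seq_along(error_groups))
  df <- data.frame(
    error = unlist(error_groups, use.names = FALSE),
    device = factor(rep(names(error_groups), lengths(error_groups))))
  fit <- stats::aov(error ~ device, data = df)
  tab <- summary(fit)[[1]]
  out <- list(anova = list(F = tab["device", "F value"],
                           df = c(tab["device", "Df"], tab["Residuals", "Df"]),
                           p = tab["device", "Pr(>F)"]),
              tukey = NULL, alpha = alpha)
  if (is.finite(out$anova$p) && out$anova$p < alpha) {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$device
    out$tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                            lwr = tk[, "lwr"], upr = tk[, "upr"],
                            p_adj = tk[, "p adj"], row.names = NULL)
  }
  structure(out, class = "device_comparison")
}

#' @export
print.device_comparison <- function(x, ...) {
  cat(sprintf("<device_comparison> one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p))
  if (is.null(x$tukey)) {
    cat(sprintf("  not significant at alpha = %.2f; Tukey HSD not run\n", x$alpha))
  } else {
    cat("  Tukey HSD pairwise differences:\n")
    print(format(x$tukey, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Full accuracy summary for one device
#'
#' @param ref A `reference_table`.
#' @param device Device label.
#' @return List with `n` (detected), `rmse`, `bias`, `rrmse`, `rbias`,
#'   `r2`, `tdr`, and the reference/estimate/error ranges.
#' @export
error_stats <- function(ref, device) {
  et <- error_table(ref, device)
  det <- et[et$detected, ]
  list(n = nrow(det),
       rmse = rmse(det$error), bias = bias(det$error),
       rrmse = rrmse(det$error, det$reference),
       rbias = rbias(det$error, det$reference),
       r2 = if (nrow(det) >= 2L) r2(det$reference, det$estimate) else NA_real_,
       tdr = detection_rate(ref, device),
       reference_range = range(et$reference),
       estimate_range = range(det$estimate),
       error_range = range(det$error))
}

#' Benchmark report across devices
#'
#' Builds the two standard report tables: a per-object table of estimates
#' and signed errors for every device, and a summary table (R^2, RMSE,
#' rRMSE, bias, rBias, ranges, N, TDR) with one column per device. When
#' two or more devices are present, device errors are also compared by
#' one-way ANOVA with a Tukey HSD post hoc test.
#'
#' @param ref A `reference_table`.
#' @param devices Devices to include; defaults to all in the table.
#' @param alpha Significance level for the comparison tests.
#' @param digits Display rounding for the per-object table (2, matching
#'   centimetre reporting); summaries keep 3 decimals. Internal computation
#'   is at full precision.
#' @return An object of class `benchmark_report`: list with `objects`
#'   (data frame), `summary` (data frame), `comparison`
#'   (`device_comparison` or `NULL`).
#' @export
report <- function(ref, devices = attr(ref, "devices"), alpha = 0.05,
                   digits = 2) {
  stopifnot(inherits(ref, "reference_table"), length(devices) >= 1L)
  objects <- data.frame(id = ref$id, reference = ref$reference)
  for (dev in devices) {
    et <- error_table(ref, dev)
    objects[[paste0(dev, "_est")]] <- round(et$estimate, digits)
    objects[[paste0(dev, "_diff")]] <- round(et$error, digits)
  }
  stats_by_dev <- lapply(devices, function(dev) error_stats(ref, dev))
  names(stats_by_dev) <- devices
  summary_df <- data.frame(
    statistic = c("R2", "RMSE", "rRMSE_pct", "Bias", "rBias_pct",
                  "Estimated_max", "Estimated_min", "Error_max", "Error_min",
                  "N", "TDR_pct"))
  for (dev in devices) {
    s <- stats_by_dev[[dev]]
    summary_df[[dev]] <- c(round(s$r2, 3), round(s$rmse, digits),
                           round(s$rrmse, 3), round(s$bias, digits),
                           round(s$rbias, 3),
                           round(s$estimate_range[2], 3),
                           round(s$estimate_range[1], 3),
                           round(s$error_range[2], 3),
                           round(s$error_range[1], 3),
                           s$n, round(s$tdr, 1))
  }
  comparison <- NULL
  if (length(devices) >= 2L) {
    groups <- lapply(devices, function(dev) {
      et <- error_table(ref, dev)
      et$error[et$detected]
    })
    names(groups) <- devices
    comparison <- tryCatch(anova_tukey(groups, alpha = alpha),
                           error = function(e) NULL)
  }
  structure(list(objects = objects, summary = summary_df,
                 comparison = comparison),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Per-object estimates and errors:\n")
  print(x$objects, row.names = FALSE)
  cat("\nSummary statistics by device:\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat("\n")
    print(x$comparison)
  }
  invisible(x)
}
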