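ref_d <- read_reference_table(lab_reference_path("diameter"))
ref_h <- read_reference_table(lab_reference_path("height"))

test_that("error records follow the signed estimate-minus-reference convention", {
  et <- error_table(ref_d, "lca_tls")
  expect_equal(et$error[et$id == "ID10"], 52.70 - 50.50)
  expect_equal(et$error[et$id == "ID10"], 2.20)
  expect_equal(bias(et$estimate - et$estimate), 0)
  ip <- error_table(ref_d, "iphone")
  expect_true(all(is.na(ip$error[ip$id %in% c("ID11", "ID12")])))
  expect_false(ip$detected[ip$id == "ID11"])
  expect_error(error_table(ref_d, "leica"), "unknown device")
})

test_that("undetected objects are excluded from RMSE and bias", {
  e <- error_table(ref_d, "iphone")$error
  expect_equal(sum(!is.na(e)), 10L)
  expect_equal(rmse(e), sqrt(mean(e[!is.na(e)]^2)))
  expect_equal(rmse(c(0, 0, 0)), 0)
  expect_equal(bias(c(0, 0, 0)), 0)
  expect_error(rmse(c(NA_real_, NA_real_)), "no detected")
  expect_equal(r2(c(1, 2, 3), c(1, 2, 3)), 1)
})

test_that("RMSE is never smaller than |bias|", {
  set.seed(20)
  for (i in 1:20) {
    e <- rnorm(sample(3:30, 1), sample(-3:3, 1), runif(1, 0.01, 2))
    expect_gte(rmse(e) + 1e-12, abs(bias(e)))
  }
  expect_equal(rmse(rep(1.3, 5)), abs(bias(rep(1.3, 5))))
})

test_that("detection rate separates detection from measurement accuracy", {
  expect_equal(round(detection_rate(ref_d, "iphone"), 1), 83.3)
  expect_equal(detection_rate(ref_d, "riegl"), 100)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,reference,d_detected,d_est", "a,1,no,", "b,2,no,"), f)
  expect_equal(detection_rate(read_reference_table(f), "d"), 0)
})

test_that("summary statistics use the population standard deviation", {
  s <- summary_stats(ref_d$reference)
  expect_equal(round(s$mean, 2), 17.78)
  expect_equal(round(s$sd, 2), 11.93)
  expect_equal(s$min, 2.6); expect_equal(s$max, 50.5)
  sl <- summary_stats(ref_h$reference)
  expect_equal(round(sl$mean, 2), 156.58)
  expect_equal(round(sl$sd, 2), 70.13)
  expect_equal(summary_stats(5)$sd, 0)
  expect_equal(summary_stats(c(1, 2, 3), sample = TRUE)$sd, 1)
  expect_error(summary_stats(numeric(0)), "empty")
})

test_that("paired t matches the closed-form statistic", {
  ref <- c(10, 10, 10); est <- ref + c(1, 2, 3)
  out <- paired_t(est, ref)
  expect_equal(out$mean_diff, 2, tolerance = 1e-12)
  expect_equal(out$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(out$df, 2)
  # oracle for the p-value and CI from the t distribution directly
  expect_equal(out$p, 2 * stats::pt(-abs(out$t), df = 2), tolerance = 1e-12)
  half <- stats::qt(0.975, 2) * stats::sd(est - ref) / sqrt(3)
  expect_equal(out$ci, 2 + c(-half, half), tolerance = 1e-9)
  expect_error(paired_t(ref, ref), "zero variance")
  expect_error(paired_t(ref + 2, ref), "zero variance")
  expect_error(paired_t(1:3, 1:4), "lengths differ")
})

test_that("ANOVA and Tukey agree with hand-computed sums of squares", {
  g <- list(a = c(2, 4, 6), b = c(3, 5, 7), c = c(10, 12, 14))
  out <- anova_tukey(g)
  # oracle: explicit between/within sums of squares
  means <- vapply(g, mean, numeric(1)); grand <- mean(unlist(g))
  ss_b <- 3 * sum((means - grand)^2)
  ss_w <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  F_oracle <- (ss_b / 2) / (ss_w / 6)
  expect_equal(out$anova$F, F_oracle, tolerance = 1e-9)
  expect_equal(out$anova$df, c(2, 6))
  expect_false(is.null(out$tukey))
  # Tukey oracle: q-based half-width and difference of means
  ms_w <- ss_w / 6
  half <- stats::qtukey(0.95, 3, 6) * sqrt(ms_w / 3)
  row_ca <- out$tukey[out$tukey$pair == "c-a", ]
  expect_equal(row_ca$diff, means["c"] - means["a"], ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(row_ca$upr - row_ca$diff, half, tolerance = 1e-9)
  expect_lt(row_ca$p_adj, 0.05)
  expect_lt(out$tukey$p_adj[out$tukey$pair == "c-b"], 0.05)
  expect_gt(out$tukey$p_adj[out$tukey$pair == "b-a"], 0.05)
})

test_that("identical groups give F = 0 and no post hoc test", {
  out <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(out$anova$F, 0, tolerance = 1e-12)
  expect_null(out$tukey)
  expect_error(anova_tukey(list(a = 1:3)), "at least 2")
  expect_error(anova_tukey(list(a = 1:3, b = 2)), "at least 2 observations")
})

test_that("with two groups the ANOVA F equals the pooled t squared", {
  set.seed(22)
  a <- rnorm(8, 0, 1); b <- rnorm(10, 1, 1)
  out <- anova_tukey(list(a = a, b = b))
  t2 <- stats::t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(out$anova$F, unname(t2), tolerance = 1e-9)
})

test_that("the report reproduces the benchmark table layout", {
  rep_d <- report(ref_d)
  expect_equal(nrow(rep_d$objects), 12L)
  expect_length(grep("_est$", names(rep_d$objects)), 4L)
  recomputed <- vapply(c("iphone", "lca_tls", "riegl", "stonex"), function(d)
    round(rmse(error_table(ref_d, d)$error), 2), numeric(1))
  expect_equal(unname(unlist(
    rep_d$summary[rep_d$summary$statistic == "RMSE", -1])),
    unname(recomputed))
  expect_equal(unname(unlist(
    rep_d$summary[rep_d$summary$statistic == "TDR_pct", -1])),
    c(83.3, 100, 100, 100))
  expect_s3_class(rep_d$comparison, "device_comparison")
  single <- report(ref_d, devices = "riegl")
  expect_null(single$comparison)
  expect_equal(ncol(single$summary), 2L)
})

test_that("DBH pipeline bias vanishes and RMSE grows with sensor noise", {
  set.seed(23)
  n_stems <- 60
  dbh_true <- runif(n_stems, 15, 40)
  est_at <- function(sigma) vapply(seq_len(n_stems), function(i) {
    sec <- circle_section(1500, R = dbh_true[i] / 200, sigma = sigma)
    dbh_from_perimeter(perimeter_polygon(sec))
  }, numeric(1))
  rmses <- c(); biases <- c()
  for (sigma in c(0, 0.005, 0.010, 0.020)) {
    e <- est_at(sigma) - dbh_true
    rmses <- c(rmses, rmse(e)); biases <- c(biases, bias(e))
  }
  expect_lt(abs(biases[1]), 0.1)   # noiseless: sub-millimetre bias
  expect_true(all(diff(rmses) > 0))
})
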