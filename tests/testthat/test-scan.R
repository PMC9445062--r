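# a small standardized case-cohort dataset shared by the scan tests
scan_fixture <- local({
  pan <- toy_panel(8)
  cfg <- cohort_config(n_cohort = 2500L, seed = 71, panel = pan,
                       n_blocks = 2L,
                       log_hr = c(age = 0.4, glucose = 0.6, M01 = 0.6))
  co <- simulate_cohort(cfg)
  d <- sample_case_cohort(co, fraction = 0.15, seed = 72)
  list(panel = pan, data = standardize_biomarkers(d, pan))
})

test_that("bh_fdr matches stats::p.adjust and flags by q-value", {
  set.seed(201)
  p <- c(runif(40), runif(10)^4)
  f <- bh_fdr(p, alpha = 0.05)
  expect_equal(f$q, p.adjust(p, "BH"), tolerance = 1e-12)
  expect_identical(f$reject, f$q <= 0.05)
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("standardization uses subcohort statistics only", {
  d <- scan_fixture$data
  sub <- d[d$in_subcohort, ]
  for (mk in c("M01", "M05")) {
    expect_equal(sd(sub[[mk]]), 1, tolerance = 1e-12)
    expect_equal(mean(sub[[mk]]), 0, tolerance = 1e-12)
  }
  sc <- attr(d, "biomarker_scaling")
  expect_setequal(sc$marker, panel_markers(scan_fixture$panel))
  expect_true(all(sc$scale > 0))
})

test_that("run_scan produces one calibrated row per marker and tier", {
  sc <- run_scan(scan_fixture$data, scan_fixture$panel,
                 tiers = c("basic", "full", "full_plus_glucose"))
  expect_equal(nrow(sc), 8L * 3L)
  expect_setequal(unique(sc$tier), c("basic", "full", "full_plus_glucose"))
  expect_true(all(sc$converged))
  expect_true(all(sc$hr > 0))
  expect_true(all(sc$lcl <= sc$hr & sc$hr <= sc$ucl))
  # planted marker is the top hit in every tier
  for (ti in unique(sc$tier)) {
    st <- sc[sc$tier == ti, ]
    expect_equal(st$biomarker[which.max(abs(st$z))], "M01")
  }
  expect_true(all(sc$significant[sc$biomarker == "M01"]))
  # q-values are computed per tier: each tier's q set matches its own BH
  st <- sc[sc$tier == "basic", ]
  expect_equal(st$q, p.adjust(st$p, "BH"), tolerance = 1e-12)
})

test_that("quartile analysis cuts at subcohort quartiles", {
  qs <- quartile_scan(scan_fixture$data, "M01", tier = "basic")
  expect_equal(qs$quartile, c("Q2", "Q3", "Q4"))
  expect_true(all(is.finite(qs$hr)))
  # monotone increasing risk across quartiles for the planted marker
  expect_gt(qs$hr[3], qs$hr[1])
  cuts <- attr(qs, "cut_points")
  sub <- scan_fixture$data[scan_fixture$data$in_subcohort, ]
  expect_equal(cuts, quantile(sub$M01, c(0.25, 0.5, 0.75), names = FALSE),
               tolerance = 1e-12)
})

test_that("subgroup scan drops degenerate covariates and reports Q", {
  res <- subgroup_scan(scan_fixture$data, "M01", "sex", tier = "basic")
  expect_equal(res$table$stratum, c("male", "female"))
  expect_true(all(c("Q", "df", "p") %in% names(res$heterogeneity)))
  expect_equal(res$heterogeneity$df, 1L)
  # manual Cochran Q from the reported rows
  w <- 1 / res$table$se^2
  bbar <- sum(w * res$table$beta) / sum(w)
  expect_equal(res$heterogeneity$Q, sum(w * (res$table$beta - bbar)^2),
               tolerance = 1e-12)
})

test_that("early-follow-up exclusion shifts entry and keeps attributes", {
  d2 <- sensitivity_exclude_early(scan_fixture$data, years = 2)
  expect_true(all(d2$time > 2))
  expect_true(all(d2$entry >= 2))
  expect_equal(attr(d2, "sampling_fraction"),
               attr(scan_fixture$data, "sampling_fraction"))
  fit <- fit_cox(d2, "M01", risk_rule = "prentice")
  expect_true(fit$converged)
  expect_lt(fit$n_events, sum(scan_fixture$data$event))
})

test_that("partial correlations remove adjuster-driven association", {
  set.seed(202)
  n <- 800
  age <- rnorm(n, 50, 10)
  d <- data.frame(age = age,
                  sex = factor(sample(c("m", "f"), n, TRUE)),
                  area = factor(sample(c("a1", "a2"), n, TRUE)))
  # two markers correlated only through age
  d$u <- 0.8 * scale(age)[, 1] + 0.6 * rnorm(n)
  d$v <- 0.8 * scale(age)[, 1] + 0.6 * rnorm(n)
  R <- partial_correlations(d, c("u", "v"))
  expect_lt(abs(R["u", "v"]), 0.1)
  expect_gt(cor(d$u, d$v), 0.4)
  expect_equal(diag(R), c(u = 1, v = 1))
})

test_that("pca screen flags an inserted extreme observation", {
  set.seed(203)
  M <- matrix(rnorm(500 * 6), 500, 6)
  M[7, ] <- 25
  ps <- pca_screen(M, k = 3, threshold = 6)
  expect_true(7 %in% ps$flagged)
  expect_equal(dim(ps$scores), c(500L, 3L))
  expect_equal(apply(ps$scores, 2, sd), c(PC1 = 1, PC2 = 1, PC3 = 1),
               tolerance = 1e-8)
})

test_that("adiposity gradients pair regression slopes with scan log HRs", {
  sc <- run_scan(scan_fixture$data, scan_fixture$panel, tiers = "fig2")
  g <- adiposity_gradient(scan_fixture$data, scan_fixture$panel, sc,
                          adiposity = "bmi")
  expect_equal(nrow(g), 8L)
  expect_equal(g$y_loghr, sc$beta[match(g$biomarker, sc$biomarker)])
  expect_true(all(is.finite(g$x_slope)))
})
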