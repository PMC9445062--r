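test_that("weighted concordance matches the brute-force pair definition", {
  set.seed(301)
  n <- 120
  d <- data.frame(time = rexp(n) + 0.1, event = rbinom(n, 1, 0.5))
  s <- rnorm(n)
  # unweighted (f = 1)
  c1 <- weighted_cindex(s, d, fraction = 1, B = 0)
  expect_equal(c1$c, harrell_oracle(d$time, d$event, s), tolerance = 1e-12)
  # with case-cohort weights
  d$is_case <- d$event == 1
  d$in_subcohort <- runif(n) < 0.5
  keep <- d$is_case | d$in_subcohort
  d2 <- d[keep, ]; s2 <- s[keep]
  w <- ifelse(d2$is_case, 1, 1 / 0.3)
  c2 <- weighted_cindex(s2, d2, fraction = 0.3, B = 0)
  expect_equal(c2$c, harrell_oracle(d2$time, d2$event, s2, w),
               tolerance = 1e-12)
})

test_that("concordance hits the boundary values for perfect and reversed rank", {
  set.seed(302)
  d <- data.frame(time = sort(rexp(60)) + 0.1,
                  event = rbinom(60, 1, 0.6))
  perfect <- -d$time
  expect_equal(weighted_cindex(perfect, d, fraction = 1, B = 0)$c, 1)
  expect_equal(weighted_cindex(-perfect, d, fraction = 1, B = 0)$c, 0)
  # constant predictor ties every pair
  expect_equal(weighted_cindex(rep(1, 60), d, fraction = 1, B = 0)$c, 0.5)
})

test_that("bootstrap CI brackets the point estimate and is reproducible", {
  set.seed(303)
  n <- 300
  d <- data.frame(time = rexp(n) + 0.1, event = rbinom(n, 1, 0.4))
  d$is_case <- d$event == 1
  d$in_subcohort <- TRUE
  s <- -d$time + rnorm(n)
  a <- weighted_cindex(s, d, fraction = 1, B = 50, seed = 9)
  b <- weighted_cindex(s, d, fraction = 1, B = 50, seed = 9)
  expect_identical(a$boot, b$boot)
  expect_lte(a$ci_low, a$c)
  expect_gte(a$ci_high, a$c)
})

test_that("model comparison detects an informative biomarker", {
  pan <- toy_panel(4)
  cfg <- cohort_config(n_cohort = 3000L, seed = 91, panel = pan,
                       n_blocks = 1L, bmi_loadings = 0, wc_loadings = 0,
                       log_hr = c(age = 0.4, glucose = 0.5, M01 = 0.9))
  d <- sample_case_cohort(simulate_cohort(cfg), fraction = 0.15, seed = 92)
  d <- standardize_biomarkers(d, pan)
  base <- fit_risk_model(d, tag = "base")
  enh <- fit_risk_model(d, biomarkers = "M01")
  expect_equal(enh$tag, "enhanced")
  cmp <- compare_models(base, enh, d, B = 100, seed = 93)
  expect_s3_class(cmp, "model_comparison")
  expect_gt(cmp$delta_c, 0)
  expect_lt(cmp$p, 0.05)
  expect_equal(cmp$table$population[1], "total")
  # subgroup rows exist for both strata of each subgrouping
  expect_true(all(c("sex:male", "sex:female", "bmi25:bmi<25") %in%
                    cmp$table$population))
  # identical models give a zero difference and p = 1
  cmp0 <- compare_models(base, base, d, B = 20, seed = 94)
  expect_equal(cmp0$delta_c, 0)
  expect_equal(cmp0$p, 1)
})

test_that("comparison refuses mismatched datasets and writes its report", {
  pan <- toy_panel(3)
  cfg <- cohort_config(n_cohort = 1500L, seed = 95, panel = pan,
                       n_blocks = 1L)
  d <- sample_case_cohort(simulate_cohort(cfg), fraction = 0.2, seed = 96)
  d <- standardize_biomarkers(d, pan)
  base <- fit_risk_model(d, tag = "base")
  enh <- fit_risk_model(d, biomarkers = "M01")
  expect_error(compare_models(base, enh, d[-1, ], B = 0),
               "not fitted on this dataset")
  cmp <- compare_models(base, enh, d, B = 20, seed = 97,
                        subgroups = FALSE)
  ft <- tempfile(fileext = ".tsv"); fj <- tempfile(fileext = ".json")
  write_comparison(cmp, ft, fj)
  tab <- read.delim(ft)
  expect_equal(nrow(tab), 1L)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$delta_c, cmp$delta_c, tolerance = 1e-12)
  unlink(c(ft, fj))
})

test_that("missing sampling fraction is an explicit error", {
  d <- data.frame(time = rexp(20) + 0.1, event = rbinom(20, 1, 0.5))
  expect_error(weighted_cindex(rnorm(20), d, B = 0),
               "sampling fraction")
})
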