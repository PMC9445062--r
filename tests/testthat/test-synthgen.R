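test_that("simulation is reproducible and respects its seed", {
  cfg <- cohort_config(n_cohort = 400L, seed = 11, panel = toy_panel(6),
                       n_blocks = 2L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- cohort_config(n_cohort = 400L, seed = 12, panel = toy_panel(6),
                        n_blocks = 2L)
  expect_false(identical(simulate_cohort(cfg2)$time, a$time))
  expect_error(simulate_cohort(cohort_config(n_cohort = 10L,
                                             panel = toy_panel(2),
                                             n_blocks = 1L)),
               "seed")
})

test_that("baseline scale is calibrated to the target incidence", {
  cfg <- cohort_config(n_cohort = 20000L, seed = 3, panel = toy_panel(4),
                       n_blocks = 2L, target_incidence = 0.1)
  co <- simulate_cohort(cfg)
  expect_gt(mean(co$event), 0.08)
  expect_lt(mean(co$event), 0.12)
  expect_true(all(co$time > 0))
  expect_true(all(co$time <= cfg$follow_up_years))
  # censored exactly at administrative end unless dropout is configured
  expect_true(all(co$time[co$event == 0] == cfg$follow_up_years))
})

test_that("biomarker latents carry the block correlation structure", {
  pan <- toy_panel(8)
  cfg <- cohort_config(n_cohort = 30000L, seed = 21, panel = pan,
                       n_blocks = 2L, within_block_cor = 0.5,
                       between_block_cor = 0.1,
                       bmi_loadings = 0, wc_loadings = 0)
  co <- simulate_cohort(cfg)
  M <- as.matrix(co[, panel_markers(pan)])
  R <- cor(M)
  within <- c(R[1, 2], R[2, 3], R[5, 6])
  between <- c(R[1, 5], R[2, 7], R[4, 8])
  expect_true(all(abs(within - 0.5) < 0.03))
  expect_true(all(abs(between - 0.1) < 0.03))
  expect_true(all(abs(apply(M, 2, sd) - 1) < 0.02))
})

test_that("planted hazard effects raise event rates in the right direction", {
  pan <- toy_panel(3)
  cfg <- cohort_config(n_cohort = 8000L, seed = 31, panel = pan,
                       n_blocks = 1L, bmi_loadings = 0, wc_loadings = 0,
                       log_hr = c(M01 = 0.8))
  co <- simulate_cohort(cfg)
  hi <- co$event[co$M01 > quantile(co$M01, 0.8)]
  lo <- co$event[co$M01 < quantile(co$M01, 0.2)]
  expect_gt(mean(hi), 2 * mean(lo))
  expect_error(
    simulate_cohort(cohort_config(n_cohort = 100L, seed = 1, panel = pan,
                                  n_blocks = 1L, log_hr = c(nope = 1))),
    "unknown covariate or measured marker")
})

test_that("case-cohort sampling keeps every case and flags the subcohort", {
  cfg <- cohort_config(n_cohort = 2000L, seed = 41, panel = toy_panel(3),
                       n_blocks = 1L)
  co <- simulate_cohort(cfg)
  d <- sample_case_cohort(co, fraction = 0.1, seed = 42)
  expect_equal(sum(d$is_case), sum(co$event))
  expect_equal(sum(d$in_subcohort), 200L)
  expect_true(all(d$event[!d$in_subcohort] == 1))
  expect_equal(attr(d, "sampling_fraction"), 0.1)
  expect_equal(sampling_fraction(d), 0.1)
  # overlap flagged, not duplicated
  expect_equal(anyDuplicated(d$id), 0L)
  # explicit n_cases subsamples the events
  d2 <- sample_case_cohort(co, subcohort_size = 150L, n_cases = 50L,
                           seed = 43)
  expect_equal(sum(d2$is_case), 50L)
  expect_true(all(d2$is_case[d2$in_subcohort & d2$event == 1]))
})

test_that("glucose marker loadings induce marker-glucose correlation", {
  pan <- toy_panel(4)
  cfg <- cohort_config(n_cohort = 20000L, seed = 51, panel = pan,
                       n_blocks = 2L,
                       glucose_marker_loadings = c(M01 = 0.5))
  co <- simulate_cohort(cfg)
  zg <- (co$glucose - cfg$glucose_mean) / cfg$glucose_sd
  expect_lt(abs(sd(zg) - 1), 0.03)
  expect_gt(cor(co$M01, co$glucose), 0.45)
  expect_lt(cor(co$M03, co$glucose), 0.3)
  expect_error(
    simulate_cohort(cohort_config(n_cohort = 100L, seed = 1, panel = pan,
                                  n_blocks = 2L,
                                  glucose_marker_loadings = c(ZZ = 0.5))),
    "unknown")
})

test_that("dataset TSV round-trips with its sampling metadata", {
  cfg <- cohort_config(n_cohort = 300L, seed = 61, panel = toy_panel(3),
                       n_blocks = 1L)
  d <- sample_case_cohort(simulate_cohort(cfg), fraction = 0.2, seed = 62)
  f <- tempfile(fileext = ".tsv")
  write_dataset_tsv(d, f)
  back <- read_dataset_tsv(f)
  expect_equal(attr(back, "sampling_fraction"), 0.2)
  expect_equal(nrow(back), nrow(d))
  expect_equal(back$time, d$time, tolerance = 1e-12)
  expect_equal(attr(back, "tsv_header")$seed, "61")
  unlink(f)
})
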