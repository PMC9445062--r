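test_that("selection requires hits in all three slab memberships", {
  pan <- toy_panel(27)
  cfg <- cohort_config(n_cohort = 4000L, seed = 81, panel = pan,
                       n_blocks = 3L,
                       log_hr = c(age = 0.4, M05 = 0.8))
  d <- sample_case_cohort(simulate_cohort(cfg), fraction = 0.15, seed = 82)
  d <- standardize_biomarkers(d, pan)
  sel_cfg <- selection_config(dims = c(3L, 3L, 3L),
                              base_covariates = c("age", "sex"))
  res <- cuboid_select(d, pan, config = sel_cfg)
  expect_s3_class(res, "selection_result")
  expect_equal(length(res$slab_z), 9L)
  expect_equal(unname(res$tested_counts["M05"]), 3L)
  expect_equal(unname(res$hit_counts["M05"]), 3L)
  expect_true("M05" %in% res$selected)
  # per-slab z tables cover exactly the slab markers
  cu <- assign_cuboid(pan, c(3L, 3L, 3L))
  for (sl in names(cu$slabs))
    expect_setequal(names(res$slab_z[[sl]]), cu$slabs[[sl]])
})

test_that("duplicated markers are pruned to the earlier panel member", {
  pan <- toy_panel(8)
  cfg <- cohort_config(n_cohort = 4000L, seed = 83, panel = toy_panel(7),
                       n_blocks = 1L, bmi_loadings = 0, wc_loadings = 0,
                       log_hr = c(M01 = 0.8))
  co <- simulate_cohort(cfg)
  # M08 is an exact copy of M01; in a 2x2x2 cuboid markers 1 and 8 sit at
  # opposite corners and never share a slab, so both can score 3 hits
  co$M08 <- co$M01
  d <- sample_case_cohort(co, fraction = 0.15, seed = 84)
  d <- standardize_biomarkers(d, pan)
  res <- cuboid_select(d, pan, cuboid = assign_cuboid(pan, c(2L, 2L, 2L)),
                       config = selection_config(
                         dims = c(2L, 2L, 2L),
                         base_covariates = c("age", "sex")))
  expect_true(all(c("M01", "M08") %in% res$pre_prune))
  expect_true("M01" %in% res$selected)
  expect_false("M08" %in% res$selected)
  expect_equal(res$pruned_pairs$retained, "M01")
  expect_equal(res$pruned_pairs$dropped, "M08")
  expect_gt(abs(res$pruned_pairs$correlation), 0.99)
})

test_that("selection config validates its inputs", {
  expect_error(selection_config(z_threshold = -1))
  expect_error(selection_config(hits_required = 4))
  expect_error(selection_config(correlation_threshold = 1.5))
  cfgd <- selection_config()
  expect_equal(cfgd$dims, c(5L, 5L, 9L))
  expect_equal(cfgd$hits_required, 3L)
})

test_that("selection results serialize to JSON and TSV", {
  pan <- toy_panel(8)
  cfg <- cohort_config(n_cohort = 2500L, seed = 85, panel = pan,
                       n_blocks = 2L, log_hr = c(age = 0.4, M02 = 0.8))
  d <- sample_case_cohort(simulate_cohort(cfg), fraction = 0.15, seed = 86)
  d <- standardize_biomarkers(d, pan)
  res <- cuboid_select(d, pan, cuboid = assign_cuboid(pan, c(2L, 2L, 2L)),
                       config = selection_config(
                         dims = c(2L, 2L, 2L),
                         base_covariates = c("age", "sex")))
  fj <- tempfile(fileext = ".json"); ft <- tempfile(fileext = ".tsv")
  write_selection_json(res, fj)
  write_selection_tsv(res, ft)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$selected, res$selected)
  expect_equal(back$dims, res$dims)
  tsv <- read.delim(ft, stringsAsFactors = FALSE)
  expect_equal(tsv$marker, res$selected)
  unlink(c(fj, ft))
})
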