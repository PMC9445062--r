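test_that("default panel has the documented composition", {
  p <- default_panel()
  expect_s3_class(p, "biomarker_panel")
  expect_equal(sum(!p$is_ratio), 146L)
  expect_equal(sum(p$is_ratio), 79L)
  expect_equal(nrow(p), 225L)
  expect_true(all(p$class %in% panel_classes()))
  # ratio definitions reference existing measured markers
  r <- p[p$is_ratio, ]
  expect_true(all(r$numerator %in% measured_markers(p)))
  expect_true(all(r$denominator %in% measured_markers(p)))
})

test_that("build_panel validates its spec", {
  spec <- data.frame(name = c("A", "B"), class = "amino_acid",
                     is_ratio = FALSE, stringsAsFactors = FALSE)
  expect_s3_class(build_panel(spec), "biomarker_panel")
  expect_error(build_panel(spec[, "name", drop = FALSE]), "lacks columns")
  expect_error(build_panel(rbind(spec, spec[1, ])), "duplicate")
  bad <- spec; bad$class <- "unobtainium"
  expect_error(build_panel(bad), "unknown biomarker class")
  rat <- data.frame(name = "A_by_C", class = "amino_acid", is_ratio = TRUE,
                    numerator = "A", denominator = "C",
                    stringsAsFactors = FALSE)
  spec$numerator <- NA_character_; spec$denominator <- NA_character_
  expect_error(build_panel(rbind(spec, rat)), "unknown measured marker")
})

test_that("compute_ratios divides and flags nonpositive denominators", {
  spec <- data.frame(
    name = c("A", "B", "A_by_B"), class = "amino_acid",
    is_ratio = c(FALSE, FALSE, TRUE),
    numerator = c(NA, NA, "A"), denominator = c(NA, NA, "B"),
    stringsAsFactors = FALSE)
  pan <- build_panel(spec)
  m <- cbind(A = c(2, 4, 6), B = c(1, 0, -2))
  out <- compute_ratios(m, pan)
  expect_equal(out[, "A_by_B"], c(2, NA, NA))
  expect_equal(attr(out, "n_invalid_denominator"), 2L)
  expect_equal(colnames(out), pan$name)
  expect_error(compute_ratios(m[, "A", drop = FALSE], pan), "lacks marker")
})

test_that("cuboid assignment covers each marker exactly three times", {
  pan <- default_panel()
  cu <- assign_cuboid(pan, c(5L, 5L, 9L))
  expect_equal(length(cu$slabs), 19L)
  counts <- table(unlist(cu$slabs))
  expect_true(all(counts == 3L))
  expect_setequal(names(counts), panel_markers(pan))
  sizes <- vapply(cu$slabs, length, 1L)
  expect_equal(sort(unique(sizes)), c(25L, 45L))
  expect_error(assign_cuboid(pan, c(2L, 2L, 2L)), "capacity")
})

test_that("cuboid permutation is seeded and leaves the RNG untouched", {
  pan <- toy_panel(8)
  set.seed(99); before <- .Random.seed
  a <- assign_cuboid(pan, c(2L, 2L, 2L), permute_seed = 7)
  expect_identical(.Random.seed, before)
  b <- assign_cuboid(pan, c(2L, 2L, 2L), permute_seed = 7)
  expect_identical(a$cells, b$cells)
  c_ <- assign_cuboid(pan, c(2L, 2L, 2L), permute_seed = 8)
  expect_false(identical(a$cells$marker, c_$cells$marker))
})

test_that("panel spec TSV round-trips", {
  pan <- default_panel()
  f <- tempfile(fileext = ".tsv")
  write_panel_spec(pan, f)
  back <- read_panel_spec(f)
  expect_equal(as.data.frame(back), as.data.frame(pan))
  unlink(f)
})
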