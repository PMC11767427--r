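test_that("load_cohort round-trips a small CSV pair and aligns samples", {
  ab_path <- withr::local_tempfile(fileext = ".csv")
  md_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,Ala,Gly,PC.aa.C34.1",
    "S1,1.5,2.0,0.8",
    "S2,1.2,<LOD,0.9",
    "S3,1.8,2.2,NA",
    "S4,1.1,2.4,0.7"
  ), ab_path)
  writeLines(c(
    "sample_id,gender,stage",
    "S1,female,control",
    "S2,female,osteopenia",
    "S3,female,osteoporosis",
    "S4,female,control"
  ), md_path)
  coh <- load_cohort(ab_path, md_path)
  expect_s3_class(coh, "ow_cohort")
  expect_equal(dim(coh), c(4L, 3L))
  expect_true(is.na(coh$abundance["S2", "Gly"])) # <LOD read as missing
  expect_true(is.na(coh$abundance["S3", "PC.aa.C34.1"]))
  expect_equal(coh$abundance["S1", "Ala"], 1.5)

  # a metadata row less: sample dropped with a warning
  writeLines(c(
    "sample_id,gender,stage",
    "S1,female,control",
    "S2,female,osteopenia",
    "S3,female,osteoporosis"
  ), md_path)
  expect_warning(coh3 <- load_cohort(ab_path, md_path), "dropping 1")
  expect_equal(nrow(coh3$abundance), 3L)

  # duplicated sample id is a hard error naming the sample
  writeLines(c(
    "sample_id,Ala", "S1,1.0", "S1,2.0"
  ), ab_path)
  expect_error(load_cohort(ab_path, md_path), "S1")
})

test_that("non-numeric abundance cells are errors naming row and column", {
  ab_path <- withr::local_tempfile(fileext = ".csv")
  md_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,Ala", "S1,1.0", "S2,oops"), ab_path)
  writeLines(c("sample_id,stage", "S1,control", "S2,control"), md_path)
  expect_error(load_cohort(ab_path, md_path), "S2.*Ala")
})

test_that("missingness filter drops >20% metabolites and imputes the rest", {
  # 20 samples, missing fractions exactly 0, .10, .20, .25, .50
  set.seed(4)
  ab <- matrix(rlnorm(100), 20, 5,
    dimnames = list(sprintf("S%02d", 1:20), paste0("M", 1:5))
  )
  for (j in 2:5) ab[seq_len(c(0, 2, 4, 5, 10)[j]), j] <- NA
  coh <- tiny_cohort(ab)
  out <- filter_missing(coh)
  expect_equal(colnames(out$abundance), c("M1", "M2", "M3"))
  expect_false(anyNA(out$abundance))
  rep <- removal_report(out)
  expect_equal(rep$kept, c(1L, 1L, 1L, 0L, 0L))
  expect_equal(rep$missing_fraction, c(0, 0.10, 0.20, 0.25, 0.50))

  # identity on a complete matrix
  coh2 <- tiny_cohort(matrix(rlnorm(40), 8, 5,
    dimnames = list(paste0("s", 1:8), paste0("m", 1:5))
  ))
  expect_equal(filter_missing(coh2)$abundance, coh2$abundance)

  # 2 of 5 missing (40%) removes the metabolite
  ab3 <- matrix(rlnorm(10), 5, 2,
    dimnames = list(paste0("s", 1:5), c("keep", "drop"))
  )
  ab3[1:2, "drop"] <- NA
  expect_equal(colnames(filter_missing(tiny_cohort(ab3))$abundance), "keep")
})

test_that("filter_missing is idempotent and supports half_min imputation", {
  set.seed(11)
  ab <- matrix(rlnorm(60), 12, 5,
    dimnames = list(paste0("s", 1:12), paste0("m", 1:5))
  )
  ab[sample(length(ab), 8)] <- NA
  coh <- tiny_cohort(ab)
  once <- filter_missing(coh)
  twice <- filter_missing(once)
  expect_equal(twice$abundance, once$abundance)

  hm <- filter_missing(coh, impute = "half_min")
  j <- which(colSums(is.na(ab)) > 0)[1]
  na_row <- which(is.na(ab[, j]))[1]
  expect_equal(
    hm$abundance[na_row, j],
    min(ab[, j], na.rm = TRUE) / 2
  )
})

test_that("median imputation respects gender strata", {
  ab <- matrix(c(
    1, 2, 3, 10, 20, NA
  ), ncol = 1, dimnames = list(paste0("s", 1:6), "m1"))
  coh <- cohort(ab, data.frame(
    sample_id = paste0("s", 1:6),
    gender = rep(c("female", "male"), each = 3)
  ))
  out <- filter_missing(coh, max_missing_fraction = 0.5)
  expect_equal(out$abundance["s6", "m1"], 15) # male median, not pooled 3
})

test_that("T-scores follow the BMD formula and are unit invariant", {
  expect_equal(t_score(0.85, 0.95, 0.12), -0.8333, tolerance = 1e-4)
  expect_equal(
    t_score(0.85, 0.95, 0.12),
    t_score(850, 950, 120) # mg/cm^2 instead of g/cm^2
  )
  expect_error(t_score(0.85, 0.95, 0), "positive")
})

test_that("stage assignment applies any-site osteoporosis and all-site control rules", {
  panel <- data.frame(
    sample_id = rep(c("A", "B", "C"), each = 3),
    site = rep(c("spine", "femoral_neck", "total_hip"), 3),
    measured = 1,
    young_mean = 1,
    young_sd = 1
  )
  # encode desired T-scores through measured = young_mean + T * SD
  tvals <- c(-1.2, -2.6, -0.5, -0.2, -0.5, -0.9, -1.5, -2.0, -0.3)
  panel$measured <- panel$young_mean + tvals * panel$young_sd
  st <- assign_stage(panel)
  expect_equal(as.character(st[["A"]]), "osteoporosis") # one site < -2.5
  expect_equal(as.character(st[["B"]]), "control") # all >= -1.0
  expect_equal(as.character(st[["C"]]), "osteopenia")
})

test_that("stage assignment partitions samples for any valid threshold pair", {
  set.seed(21)
  panel <- data.frame(
    sample_id = rep(sprintf("P%02d", 1:40), each = 2),
    site = rep(c("spine", "hip"), 40),
    measured = rnorm(80, 0.9, 0.15),
    young_mean = 0.95,
    young_sd = 0.12
  )
  for (thr in list(c(-2.5, -1), c(-3, -0.5), c(-1.5, -1.4))) {
    st <- assign_stage(panel, thr[1], thr[2])
    expect_equal(length(st), 40L)
    expect_false(anyNA(st))
  }
  expect_error(assign_stage(panel, -1, -2.5), "below")
})

test_that("incomplete reference sites are skipped; no usable site errors", {
  panel <- data.frame(
    sample_id = c("A", "A", "B"),
    site = c("spine", "hip", "spine"),
    measured = c(0.8, 0.9, 0.85),
    young_mean = c(NA, 0.95, NA),
    young_sd = c(0.12, 0.12, 0.12)
  )
  expect_warning(st <- assign_stage(panel[1:2, ]), "skipped")
  expect_equal(length(st), 1L)
  expect_warning(expect_error(assign_stage(panel), "no usable"), "skipped")
})
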