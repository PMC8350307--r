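test_that("cohort specs validate counts and override bounds", {
  s <- cohort_spec(c(ABRS = 10), seed = 3)
  expect_identical(sum(s$counts), 10L)
  expect_error(cohort_spec(c(ABRS = -1)), "non-negative")
  expect_error(cohort_spec(c(FLU = 5)), "unknown categor")
  expect_error(cohort_spec(c(ABRS = 2), override_count = 3),
               "override_count")
})

test_that("the study-replica preset carries the published category structure", {
  s <- study_replica_spec()
  expect_identical(sum(s$counts), 1465L)
  expect_identical(unname(s$counts[c("COMMON_COLD", "POST_VIRAL_ARS", "ABRS")]),
                   c(335L, 186L, 101L))
  # 843 chronic patients, 13 of them antibiotic-indicated
  expect_identical(sum(s$counts[c("CRS", "CRS_MACROLIDE_ELIGIBLE",
                                  "CRS_COMPLICATION")]), 843L)
  expect_identical(sum(s$counts[c("CRS_MACROLIDE_ELIGIBLE",
                                  "CRS_COMPLICATION")]), 13L)
})

test_that("sampled profiles satisfy their generating category's predicates", {
  set.seed(5)
  for (i in 1:50) {
    p <- sample_profile("ABRS")
    expect_gte(count_abrs_signs(p), 3L)
    expect_true(meets_abrs_temporal_criterion(p))
    expect_identical(classify_course(p$duration_days), "ACUTE")
  }
  for (i in 1:50) {
    p <- sample_profile("CRS_MACROLIDE_ELIGIBLE")
    expect_identical(p$nasal_polyps, "no")
    expect_identical(p$serum_ige_low, "yes")
    expect_true(p$refractory_to_incs)
  }
})

test_that("round trip: every sample classifies back to its generating category", {
  rs <- epos_ruleset()
  for (seed in c(2, 17, 301)) {
    set.seed(seed)
    for (cat in diagnosis_categories()) {
      for (i in 1:70) {
        p <- sample_profile(cat)
        expect_identical(infer(p, rs)$category, cat)
      }
    }
  }
})

test_that("generated cohorts conserve counts and labels", {
  spec <- cohort_spec(c(COMMON_COLD = 8, ABRS = 5, CRS = 7), seed = 9)
  cohort <- generate_cohort(spec)
  expect_identical(nrow(cohort), 20L)
  expect_identical(as.integer(table(cohort$true_category)[c("ABRS",
                                                            "COMMON_COLD",
                                                            "CRS")]),
                   c(5L, 8L, 7L))
  expect_identical(cohort$reference_label[cohort$true_category == "ABRS"],
                   rep("ANTIBIOTIC", 5))
  expect_identical(anyDuplicated(cohort$patient_id), 0L)

  expect_identical(nrow(generate_cohort(cohort_spec(c(ABRS = 0)))), 0L)
})

test_that("generation is byte-identical for identical specs", {
  spec <- cohort_spec(c(ABRS = 10, CRS = 10), override_count = 3, seed = 1)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, f1, seed = 1)
  write_cohort(c2, f2, seed = 1)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the symptom vectors
  expect_false(identical(
    generate_cohort(cohort_spec(c(ABRS = 10, CRS = 10), 3, seed = 2)), c1))
})

test_that("generate_cohort leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(cohort_spec(c(CRS = 5), seed = 77)))
  expect_identical(.Random.seed, before)
})

test_that("overrides only flip non-antibiotic reference labels", {
  spec <- cohort_spec(c(COMMON_COLD = 10, ABRS = 5), override_count = 10,
                      seed = 4)
  cohort <- generate_cohort(spec)
  ov <- cohort$specialist_override_antibiotic
  expect_identical(sum(ov), 10L)
  expect_identical(cohort$true_category[ov], rep("COMMON_COLD", 10))
  expect_identical(cohort$reference_label[ov], rep("ANTIBIOTIC", 10))
  expect_true(all(nzchar(cohort$override_reason[ov])))
  expect_false(any(nzchar(cohort$override_reason[!ov])))
  # more overrides than non-antibiotic patients cannot be honoured
  expect_error(generate_cohort(cohort_spec(c(COMMON_COLD = 2, ABRS = 5),
                                           override_count = 3, seed = 1)),
               "exceeds")
})

test_that("cohort CSV round trip preserves the data and the seed header", {
  cohort <- generate_cohort(cohort_spec(c(POST_VIRAL_ARS = 6, CRS = 4),
                                        seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path, seed = 8)
  expect_match(readLines(path, n = 1), "^# seed: 8$")
  back <- read_cohort(path)
  expect_identical(back$duration_days, cohort$duration_days)
  expect_identical(back$reference_label, cohort$reference_label)
  expect_identical(back$nasal_polyps, cohort$nasal_polyps)
  expect_equal(back$fever_celsius, cohort$fever_celsius, tolerance = 1e-6)
})

test_that("cohort specs load from JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(counts = list(ABRS = 4, CRS = 2),
                            override_count = 1, seed = 6),
                       path, auto_unbox = TRUE)
  s <- read_cohort_spec(path)
  expect_identical(unname(s$counts[c("ABRS", "CRS")]), c(4L, 2L))
  expect_identical(s$override_count, 1L)
  expect_identical(s$seed, 6L)
})
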