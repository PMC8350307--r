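rs_epos <- epos_ruleset()

test_that("forward chaining reaches the fixpoint of an abstract chain", {
  abc <- ruleset(list(rule("r1", "A", "B", 1), rule("r2", "B", "C", 2)),
                 facts = c("A", "B", "C"))
  res <- fire_rules("A", abc)
  expect_setequal(res$facts, c("A", "B", "C"))
  expect_identical(res$fired, c("r1", "r2"))

  empty <- ruleset(list(), facts = c("A"))
  expect_identical(fire_rules("A", empty)$fired, character(0))
})

test_that("rule sets reject undeclared facts and duplicate ids", {
  expect_error(ruleset(list(rule("r1", "A", "Z", 1)), facts = c("A")),
               "undeclared fact")
  expect_error(ruleset(list(rule("r1", "A", "B", 1), rule("r1", "B", "A", 2)),
                       facts = c("A", "B")),
               "duplicate rule id")
  expect_error(fire_rules("not_a_fact", rs_epos), "undeclared seed fact")
})

test_that("fixpoint is order-independent under permuted priorities", {
  profiles <- list(acute_with_signs(14, 4), acute_with_signs(14, 2),
                   acute_with_signs(5, 0), chronic_profile(postop = TRUE),
                   chronic_profile(polyps = "no", ige = "yes",
                                   refractory = TRUE),
                   chronic_profile())
  set.seed(11)
  for (rep in 1:5) {
    prio <- sample(100L)[seq_along(rs_epos$rules)]
    scrambled <- ruleset(
      lapply(seq_along(rs_epos$rules), function(i) {
        r <- rs_epos$rules[[i]]
        rule(r$id, r$antecedent, r$consequent, prio[i])
      }),
      rs_epos$facts)
    for (p in profiles)
      expect_identical(fire_rules(p, scrambled)$facts,
                       fire_rules(p, rs_epos)$facts)
  }
})

test_that("fired-rule log is ordered by (priority, rule id)", {
  tie <- ruleset(list(rule("b", "A", "B", 5), rule("a", "A", "C", 5)),
                 facts = c("A", "B", "C"))
  expect_identical(fire_rules("A", tie)$fired, c("a", "b"))
})

test_that("course classification puts the 12-week boundary on the chronic side", {
  expect_identical(classify_course(30), "ACUTE")
  expect_identical(classify_course(83), "ACUTE")
  expect_identical(classify_course(84), "CHRONIC")
  expect_identical(classify_course(90), "CHRONIC")
  expect_error(classify_course(-1), "non-negative")
})

test_that("cardinal sign count uses strict fever threshold and ignores unknowns", {
  expect_identical(count_abrs_signs(acute_with_signs(14, 5)), 5L)
  expect_identical(count_abrs_signs(acute_with_signs(14, 0)), 0L)
  p3 <- symptom_profile("t", 14, discoloured_discharge = TRUE,
                        fever_celsius = 38.6,
                        inflammatory_markers_elevated = "yes")
  expect_identical(count_abrs_signs(p3), 3L)
  # fever of exactly 38.0 is not "more than 38"
  expect_identical(count_abrs_signs(symptom_profile("t", 14,
                                                    fever_celsius = 38.0)), 0L)
  expect_identical(count_abrs_signs(
    symptom_profile("t", 14, inflammatory_markers_elevated = "unknown")), 0L)
})

test_that("temporal criterion: more than 10 days, or worsening after day 5", {
  expect_true(meets_abrs_temporal_criterion(symptom_profile("t", 11)))
  expect_false(meets_abrs_temporal_criterion(symptom_profile("t", 10)))
  expect_true(meets_abrs_temporal_criterion(
    symptom_profile("t", 7, worsening_after_day5 = TRUE)))
})

test_that("infer assigns the documented category in each canonical scenario", {
  cases <- list(
    list(acute_with_signs(5, 0), "COMMON_COLD"),
    list(acute_with_signs(14, 2), "POST_VIRAL_ARS"),
    list(acute_with_signs(14, 4), "ABRS"),
    list(acute_with_signs(7, 4, worsening = TRUE), "ABRS"),
    list(chronic_profile(120, polyps = "no", ige = "yes", refractory = TRUE),
         "CRS_MACROLIDE_ELIGIBLE"),
    list(chronic_profile(120), "CRS"),
    list(chronic_profile(120, polyps = "no", ige = "yes", refractory = TRUE,
                         postop = TRUE), "CRS_COMPLICATION")
  )
  for (cs in cases) {
    d <- infer(cs[[1]], rs_epos)
    expect_identical(d$category, cs[[2]])
    expect_gt(length(d$fired_rules), 0)
  }
})

test_that("unknown chronic modifiers fall back to plain CRS", {
  # macrolide eligibility needs all three conditions affirmed, not unknown
  expect_identical(infer(chronic_profile(100, polyps = "unknown", ige = "yes",
                                         refractory = TRUE), rs_epos)$category,
                   "CRS")
  expect_identical(infer(chronic_profile(100, polyps = "no", ige = "unknown",
                                         refractory = TRUE), rs_epos)$category,
                   "CRS")
})

test_that("the shipped rule file round-trips through read_ruleset", {
  path <- system.file("extdata", "epos2012_rules.json", package = "eposcds")
  rs2 <- read_ruleset(path)
  expect_identical(vapply(rs2$rules, `[[`, character(1), "id"),
                   vapply(rs_epos$rules, `[[`, character(1), "id"))
  expect_length(rs2$rules, 8L)
})
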