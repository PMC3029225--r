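test_that("PTA is the mean of the five audiometric thresholds", {
  expect_equal(compute_pta(c(60, 60, 60, 60, 60)), 60)
  expect_equal(compute_pta(c(50, 60, 70, 80, 90)), 70)
  expect_equal(compute_pta(c(0, 0, 0, 0, 0)), 0)
  expect_error(compute_pta(c(60, 60)), "five")
  expect_error(compute_pta(c(60, 60, 60, 60, -1)), "negative")
})

test_that("severity grading follows the five-grade clinical scale", {
  expect_equal(grade_severity(98), "profound")
  expect_equal(grade_severity(30), "mild")
  expect_equal(grade_severity(c(25, 26, 40, 41, 70, 71, 90, 91)),
               c("normal", "mild", "mild", "moderate", "moderate",
                 "severe", "severe", "profound"))
  # monotone non-decreasing in PTA
  g <- grade_severity(seq(0, 120, by = 0.5))
  ranks <- match(g, severity_levels())
  expect_true(all(diff(ranks) >= 0))
})

test_that("worse-ear grading matches 42 of 44 clinical labels, flagging the boundary sitters", {
  gc <- grade_concordance(fx_subjects)
  expect_equal(gc$n_agree, 42L)
  expect_setequal(gc$discordant, c("FE122-III-2", "NB038-III-1"))
  # both discrepancies sit exactly on a grade boundary (71/70 and 90/91)
  worse <- pmax(fx_subjects$pta_right_db, fx_subjects$pta_left_db)
  expect_true(all(worse[fx_subjects$subject_id %in% gc$discordant] %in%
                    c(71, 90)))
})

test_that("synthetic cohort reproduces the headline frequencies", {
  coh <- generate_cohort(fx_ref, default_cohort_spec(fx_variants, seed = 2),
                         sequences = FALSE)
  s <- coh$subjects
  f1555 <- variant_frequency(s, "1555A>G")
  expect_equal(f1555$carrier_count, 33L)
  expect_equal(f1555$percent, 7.5)
  fexp <- variant_frequency(s, "1555A>G", subset = s$exposed)
  expect_equal(fexp$carrier_count, 21L)
  expect_equal(fexp$percent, 21.4)
  f1494 <- variant_frequency(s, "1494C>T")
  expect_equal(f1494$percent, 0.45)
  ef <- exposure_fraction(s)
  expect_equal(ef$carrier_count, 98L)
  expect_equal(ef$percent, 22.3)
  expect_equal(variant_frequency(s, "9999X>Y")$percent, 0)
  expect_error(variant_frequency(s, "1555A>G", subset = rep(FALSE, nrow(s))),
               "empty")
})

test_that("severity histograms partition the subgroups", {
  coh <- generate_cohort(fx_ref, default_cohort_spec(fx_variants, seed = 2),
                         sequences = FALSE)
  s <- coh$subjects
  exp_hist <- severity_summary(s, s$exposed)
  unexp_hist <- severity_summary(s, !s$exposed)
  expect_equal(unname(exp_hist[c("severe", "profound")]), c(22L, 76L))
  expect_equal(unname(unexp_hist[c("moderate", "severe", "profound")]),
               c(26L, 167L, 149L))
  expect_equal(sum(exp_hist), 98L)
  expect_equal(sum(unexp_hist), 342L)
  # recorded severities agree with worse-ear grading by construction
  expect_equal(grade_concordance(s)$n_agree, nrow(s))
})

test_that("attributable fraction reports the exact exposed-carrier rate", {
  coh <- generate_cohort(fx_ref, default_cohort_spec(fx_variants, seed = 2),
                         sequences = FALSE)
  cls <- classify_all(fx_variants, model = fx_model, ref = fx_ref)
  classification <- setNames(cls$table$category, cls$table$name)
  af <- attributable_fraction(coh$subjects, classification)
  expect_equal(af$carrier_count, 27L)
  expect_equal(af$denominator, 98L)
  expect_equal(af$percent, 27.6)
  # empty pathogenic set counts nobody
  none <- attributable_fraction(coh$subjects, classification,
                                pathogenic_categories = character())
  expect_equal(none$percent, 0)
  expect_error(attributable_fraction(coh$subjects, classification["1555A>G"]),
               "unclassified")
})
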