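test_that("conservation targets are hit exactly and deterministically", {
  spec <- conservation_spec(c(`1555` = 12, `1009` = 3, `752` = 14), seed = 9)
  a1 <- generate_primate_alignment(fx_ref, spec)
  a2 <- generate_primate_alignment(fx_ref, spec)
  expect_identical(a1$mat, a2$mat)
  expect_equal(conservation_index(a1, 1555)$n_matching, 12L)
  expect_equal(conservation_index(a1, 1009)$n_matching, 3L)
  expect_equal(conservation_index(a1, 752)$n_matching, 14L)
  expect_error(conservation_spec(c(`1555` = 0)), "impossible")
  expect_error(generate_primate_alignment(
    fx_ref, conservation_spec(c(`9999` = 5))), "outside region")
})

test_that("plant_variants edits exactly the requested sites", {
  s <- plant_variants(fx_ref, "1555A>G")
  j <- 1555 - fx_ref$region_start + 1
  expect_equal(substr(s, j, j), "G")
  expect_equal(nchar(s), 954L)
  diffs <- which(strsplit(s, "")[[1]] !=
                   strsplit(region_sequence(fx_ref), "")[[1]])
  expect_equal(diffs, j)
  expect_equal(plant_variants(fx_ref, character()), region_sequence(fx_ref))
  expect_equal(nchar(plant_variants(fx_ref, "961insC")), 955L)
  expect_error(plant_variants(fx_ref, "1555C>G"), "ref-base mismatch")
  expect_error(plant_variants(fx_ref, c("1555A>G", "1555A>C")), "overlap")
})

test_that("cohort generation is a pure function of (spec, seed)", {
  spec <- default_cohort_spec(fx_variants, seed = 4)
  g1 <- generate_cohort(fx_ref, spec, sequences = FALSE)
  g2 <- generate_cohort(fx_ref, spec, sequences = FALSE)
  expect_identical(g1$subjects, g2$subjects)
  expect_identical(g1$manifest$realized_plan, g2$manifest$realized_plan)
  # realized counts equal the plan
  expect_equal(g1$manifest$realized_plan$case_carriers,
               spec$variant_plan$case_carriers)
  expect_equal(g1$manifest$realized_plan$control_carriers,
               spec$variant_plan$control_carriers)
  planned_exposed <- spec$variant_plan$exposed_carriers
  got_exposed <- g1$manifest$realized_plan$exposed_carriers
  expect_equal(got_exposed[!is.na(planned_exposed)],
               planned_exposed[!is.na(planned_exposed)])
  # known/putative carriers are mutually exclusive
  excl <- unlist(g1$manifest$case_carriers[spec$exclusive])
  expect_equal(anyDuplicated(excl), 0L)
})

test_that("infeasible plans are rejected", {
  expect_error(cohort_spec(n_cases = 5, n_controls = 5, n_exposed = 2,
                           variant_plan = data.frame(
                             name = "1555A>G", case_carriers = 9L,
                             control_carriers = 0L),
                           severity_plan = list(exposed = c(profound = 2),
                                                unexposed = c(severe = 3))),
               "infeasible")
  expect_error(cohort_spec(n_cases = 5, n_controls = 5, n_exposed = 2,
                           variant_plan = data.frame(
                             name = "1555A>G", case_carriers = 1L,
                             control_carriers = 0L),
                           severity_plan = list(exposed = c(profound = 1),
                                                unexposed = c(severe = 3))),
               "sum to subgroup")
})

test_that("generated sequences re-call to the planted counts", {
  spec <- cohort_spec(
    n_cases = 10, n_controls = 5, n_exposed = 3,
    variant_plan = data.frame(
      name = c("1555A>G", "961insC", "709G>A"),
      case_carriers = c(2L, 3L, 4L), control_carriers = c(0L, 2L, 1L),
      exposed_carriers = c(2L, NA, NA)),
    severity_plan = list(exposed = c(profound = 3),
                         unexposed = c(severe = 4, moderate = 3)),
    exclusive = "1555A>G", seed = 21)
  g <- generate_cohort(fx_ref, spec)
  case_calls <- aggregate_calls(call_cohort(g$case_seqs, fx_ref))
  expect_equal(case_calls[c("1555A>G", "961insC", "709G>A")],
               c(`1555A>G` = 2L, `961insC` = 3L, `709G>A` = 4L))
  ctrl_calls <- aggregate_calls(call_cohort(g$control_seqs, fx_ref))
  expect_equal(ctrl_calls[c("961insC", "709G>A")],
               c(`961insC` = 2L, `709G>A` = 1L))
  expect_false("1555A>G" %in% names(ctrl_calls))
})

test_that("audiograms honor the requested PTA exactly", {
  set.seed(5)
  for (pta in c(0, 12, 30, 55, 80, 105)) {
    th <- generate_audiogram(pta)
    expect_length(th, 5L)
    expect_true(all(th >= 0))
    expect_equal(compute_pta(th), pta)
    expect_equal(grade_severity(compute_pta(th)), grade_severity(pta))
  }
})
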