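cfg <- classifier_config()
cls <- classify_all(fx_variants, cfg, model = fx_model, ref = fx_ref)

test_that("criteria evaluate from integer counts", {
  t747 <- cls$table[cls$table$name == "747A>G", ]
  expect_true(t747$c1_absent_in_controls)
  expect_true(t747$c2_ci_above_threshold)
  expect_equal(t747$c3_structural_evidence, "stem_wc_change")
  t709 <- cls$table[cls$table$name == "709G>A", ]
  expect_false(t709$c1_absent_in_controls)
  t1009 <- cls$table[cls$table$name == "1009C>T", ]
  expect_false(t1009$c1_absent_in_controls)
  expect_false(t1009$c2_ci_above_threshold)
  # loop variant with very high conservation gets the loop evidence tier
  t1027 <- cls$table[cls$table$name == "1027A>G", ]
  expect_equal(t1027$c3_structural_evidence, "loop_high_ci")
  expect_error(evaluate_criteria(data.frame(name = "x", control_count = 0)),
               "missing CI")
})

test_that("category resolution follows registry, criteria, markers", {
  got <- setNames(cls$table$category, cls$table$name)
  expect_equal(unname(got["1555A>G"]), "known_pathogenic")
  # registry overrides criteria: one control carrier does not demote it
  expect_equal(unname(got["1095T>C"]), "known_pathogenic")
  expect_equal(unname(got["1027A>G"]), "putative_deafness_associated")
  expect_equal(unname(got["663A>G"]), "haplogroup_polymorphism")
  expect_equal(unname(got["961insC"]), "polymorphism")
  expect_equal(unname(got["961T>C"]), "polymorphism")
})

test_that("catalogue summary reproduces the published counts", {
  expect_equal(cls$summary$n_variants, 41L)
  expect_equal(cls$summary$n_absent_in_controls, 19L)
  expect_equal(cls$summary$n_control_freq_lt1, 8L)
  expect_equal(cls$summary$n_ci_above_threshold, 18L)
  expect_equal(cls$summary$n_criteria12, 7L)
  put <- cls$table$name[cls$table$category == "putative_deafness_associated"]
  expect_setequal(put, c("747A>G", "839A>G", "1027A>G", "1310C>T", "1413T>C"))
  # categories partition the catalogue
  expect_equal(cls$summary$known_pathogenic +
                 cls$summary$putative_deafness_associated +
                 cls$summary$haplogroup_polymorphism +
                 cls$summary$polymorphism, 41L)
  empty <- classify_all(fx_variants[0, ], cfg)
  expect_equal(empty$summary$n_variants, 0L)
  expect_equal(empty$summary$n_criteria12, 0L)
})

test_that("a reduced registry exposes the criteria-only putative set", {
  cfg2 <- classifier_config(known_pathogenic_registry = c("1555A>G", "1494C>T"))
  cls2 <- classify_all(fx_variants, cfg2, model = fx_model, ref = fx_ref)
  put <- cls2$table$name[cls2$table$category == "putative_deafness_associated"]
  expect_length(put, 5L)
  expect_equal(cls2$summary$n_criteria12, 7L)
})

test_that("classification is monotone under control-count and CI perturbation", {
  put_names <- cls$table$name[cls$table$category ==
                                "putative_deafness_associated"]
  for (nm in put_names) {
    rec <- fx_variants[fx_variants$name == nm, ]
    rec$control_count <- rec$control_count + sample(1:20, 1)
    expect_false(classify(rec, cfg)$category == "putative_deafness_associated",
                 info = paste(nm, "with controls"))
    rec2 <- fx_variants[fx_variants$name == nm, ]
    rec2$ci_percent <- NULL
    rec2$n_matching <- cfg$ci_threshold_species - 1L
    expect_false(classify(rec2, cfg)$category == "putative_deafness_associated",
                 info = paste(nm, "below CI threshold"))
  }
  # and never the reverse: zeroing controls on a high-CI polymorphism
  # promotes it, which is the expected direction
  rec <- fx_variants[fx_variants$name == "752C>T", ]
  rec$control_count <- 0L
  expect_equal(classify(rec, cfg)$category, "putative_deafness_associated")
})
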