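test_that("packaged reference loads with the documented geometry", {
  expect_s3_class(fx_ref, "MtReference")
  expect_equal(fx_ref$amplicon_start, 618L)
  expect_equal(fx_ref$amplicon_end, 2007L)
  expect_equal(nchar(region_sequence(fx_ref)),
               fx_ref$region_end - fx_ref$region_start + 1)
  expect_equal(nchar(region_sequence(fx_ref)), 954L)
  expect_equal(ref_base(fx_ref, 1555), "A")
  expect_equal(ref_base(fx_ref, 1494), "C")
})

test_that("reference loading rejects bad input with named failures", {
  two <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), two)
  expect_error(load_reference(two), "multiple records")
  expect_error(load_reference(tempfile()), "missing file")
  expect_error(mt_reference("x", "ACGX", 2, 3, 1, 4), "alphabet")
  expect_error(mt_reference("x", "ACGT", 1, 5, 1, 4), "nested")
})

test_that("variant catalogue fixture has the published marginals", {
  expect_equal(nrow(fx_variants), 41L)
  expect_equal(sum(fx_variants$control_count == 0), 19L)
  expect_equal(sum(!fx_variants$previously_reported), 2L)
  r1555 <- fx_variants[fx_variants$name == "1555A>G", ]
  expect_equal(r1555$case_count, 33L)
  expect_equal(r1555$control_count, 0L)
  # duplicate replacement rejected, empty file tolerated
  dup <- rbind(fx_variants, fx_variants[1, ])
  p <- tempfile(fileext = ".tsv"); write_variant_table(dup, p)
  expect_error(load_variant_table(p), "duplicate")
  empty <- tempfile(fileext = ".tsv"); file.create(empty)
  expect_equal(nrow(load_variant_table(empty)), 0L)
})

test_that("tables round-trip through write and re-load", {
  p <- tempfile(fileext = ".tsv")
  write_variant_table(fx_variants, p)
  expect_equal(load_variant_table(p), fx_variants)
  p2 <- tempfile(fileext = ".tsv")
  write_subject_table(fx_subjects, p2)
  expect_equal(load_subject_table(p2), fx_subjects)
})

test_that("subject table fixture matches the clinical records", {
  expect_equal(nrow(fx_subjects), 44L)
  fe003 <- fx_subjects[fx_subjects$subject_id == "FE003-IV-1", ]
  expect_equal(fe003$pta_right_db, 98)
  expect_true(fe003$exposed)
  zx039 <- fx_subjects[fx_subjects$subject_id == "ZX039-IV-1", ]
  expect_equal(zx039$gjb2, "235DelC/299DelAT")
  expect_equal(sum(fx_subjects$variant == "1555A>G"), 33L)
  bad <- fx_subjects; bad$severity[1] <- "catastrophic"
  p <- tempfile(fileext = ".tsv"); write_subject_table(bad, p)
  expect_error(load_subject_table(p), "severity")
})

test_that("haplogroup registry has 13 markers across 8 haplogroups", {
  expect_length(fx_markers, 13L)
  expect_equal(length(unique(fx_markers)), 8L)
  expect_equal(unname(fx_markers["663A>G"]), "A")
  expect_equal(unname(fx_markers["1541T>C"]), "R5b")
})

test_that("structure model validates pair geometry and covers all arrows", {
  arrows <- fx_variants$position[!is.na(fx_variants$wc_arrow)]
  expect_length(arrows, 17L)
  covered <- c(fx_model$pairs$pos5, fx_model$pairs$pos3)
  expect_true(all(arrows %in% covered))
  # the apposed-but-unpaired A-site pair is in the model
  i <- which(fx_model$pairs$pos5 == 1494)
  expect_equal(fx_model$pairs$pos3[i], 1555L)
  expect_false(fx_model$pairs$wild_paired[i])
  expect_error(structure_model(data.frame(pos5 = c(700, 700), pos3 = c(800, 900),
                                          wild_paired = TRUE)),
               "more than one pair")
  expect_error(structure_model(data.frame(pos5 = 800, pos3 = 700,
                                          wild_paired = TRUE)),
               "pos5")
  expect_error(structure_model(data.frame(pos5 = 663, pos3 = 700,
                                          wild_paired = FALSE), ref = fx_ref),
               "disagrees")
})

test_that("primate alignment objects validate row geometry", {
  aln <- generate_primate_alignment(fx_ref, conservation_spec(c(`1555` = 12)))
  expect_s3_class(aln, "PrimateAlignment")
  expect_equal(nrow(aln$mat), 14L)
  p <- tempfile(fileext = ".fasta")
  write_primate_alignment(aln, p)
  re <- load_primate_alignment(p, region_start = fx_ref$region_start,
                               ref = fx_ref)
  expect_equal(re$mat, aln$mat)
  expect_error(primate_alignment(c("a", "b"), c("ACGT", "ACG"), "a", 1),
               "unequal length")
  expect_error(primate_alignment(c("a", "b"), c("ACGT", "ACGT"), "zz", 1),
               "not found")
})
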