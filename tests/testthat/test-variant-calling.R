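test_that("identical input aligns with no mismatches and no gaps", {
  aln <- align_to_reference(region_sequence(fx_ref), fx_ref)
  expect_equal(aln$identity, 1)
  expect_false(grepl("-", aln$pattern))
  calls <- extract_variants(aln, fx_ref)
  expect_equal(nrow(calls), 0L)
})

test_that("a single planted substitution gives exactly one mismatch column", {
  # independent dynamic-programming oracle on a 160-nt slice
  mini <- mini_reference(fx_ref, 1450, 1609)
  subj <- with_substitution(mini, 1555, "G")
  oracle <- nw_score(subj, region_sequence(mini))
  expect_equal(oracle, (160 - 1) * 1 + (-1))  # 159 matches, 1 mismatch
  aln <- align_to_reference(subj, mini)
  expect_equal(aln$score, oracle)
  cols <- strsplit(aln$pattern, "")[[1]] != strsplit(aln$subject, "")[[1]]
  expect_equal(sum(cols), 1L)
  calls <- extract_variants(aln, mini, aliases = NULL)
  expect_equal(calls$name, "1555A>G")
})

test_that("variant naming follows the field's conventions", {
  expect_equal(variant(1494, "C", "T")$name, "1494C>T")
  expect_equal(variant(235, "C", "")$name, "235delC")
  expect_equal(variant(299, "AT", "")$name, "299delAT")
  expect_equal(name_variant(956, "", "C", "insertion", fx_aliases), "961insC")
  expect_error(variant(100, "A", "A"), "ref != alt")
  # parsing inverts naming, resolving legacy aliases to canonical coords
  v <- parse_variant_name("961insC", fx_aliases)
  expect_equal(v$position, 956L)
  expect_equal(v$name, "961insC")
  rt <- parse_variant_name(c("1555A>G", "299delAT"))
  expect_equal(rt$name, c("1555A>G", "299delAT"))
  expect_error(parse_variant_name("garbage"), "unparseable")
})

test_that("insertion calls are normalized independently of gap placement", {
  # an extra C anywhere in the 957-960 homopolymer is the same molecule;
  # every placement must yield the single legacy-named call 961insC
  for (at in 956:960) {
    subj <- with_insertion_after(fx_ref, at, "C")
    calls <- extract_variants(align_to_reference(subj, fx_ref), fx_ref)
    expect_equal(calls$name, "961insC")
    expect_equal(calls$position, 956L)
  }
  # idempotence: re-calling the planted sequence gives the same call
  planted <- plant_variants(fx_ref, "961insC")
  expect_equal(extract_variants(align_to_reference(planted, fx_ref),
                                fx_ref)$name, "961insC")
})

test_that("deletions are called and left-normalized", {
  s <- strsplit(region_sequence(fx_ref), "")[[1]]
  j <- 1200 - fx_ref$region_start + 1
  subj <- paste(s[-j], collapse = "")
  calls <- extract_variants(align_to_reference(subj, fx_ref), fx_ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$kind, "deletion")
  # the named position's deleted base matches the reference
  expect_equal(ref_base(fx_ref, calls$position), calls$ref)
})

test_that("divergent and reverse-complement input is rejected, not miscalled", {
  set.seed(42)
  junk <- paste(sample(c("A", "C", "G", "T"), 954, TRUE), collapse = "")
  expect_error(align_to_reference(junk, fx_ref), "unalignable")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(region_sequence(fx_ref))))
  expect_error(align_to_reference(rc, fx_ref), "reverse-complement")
  expect_error(align_to_reference("ACGT", fx_ref), "length")
})

test_that("N at a variant position yields a no-call, not a variant", {
  subj <- with_substitution(fx_ref, 1555, "N")
  calls <- extract_variants(align_to_reference(subj, fx_ref), fx_ref)
  expect_equal(nrow(calls), 0L)
  expect_equal(attr(calls, "no_calls"), 1555L)
})

test_that("cohort calling aggregates carriers by subject", {
  seqs <- c(S1 = plant_variants(fx_ref, "1555A>G"),
            S2 = region_sequence(fx_ref),
            S3 = region_sequence(fx_ref))
  calls <- call_cohort(seqs, fx_ref)
  expect_equal(aggregate_calls(calls), c("1555A>G" = 1L))
  expect_error(call_cohort(seqs[c(1, 1)], fx_ref), "duplicate")
  expect_error(call_cohort(character(), fx_ref), "empty input")
})

test_that("plant-and-recall round-trips random substitution sets", {
  positions <- setdiff(fx_ref$region_start:fx_ref$region_end, 956:961)
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(1:6, 1)
    pos <- sort(sample(positions, k))
    vars <- vapply(pos, function(p) {
      refb <- ref_base(fx_ref, p)
      paste0(p, refb, ">", sample(setdiff(c("A", "C", "G", "T"), refb), 1))
    }, character(1))
    planted <- plant_variants(fx_ref, vars)
    calls <- extract_variants(align_to_reference(planted, fx_ref), fx_ref)
    expect_equal(calls$name, vars)
  }
})
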