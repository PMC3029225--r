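# shared fixtures, loaded once per test run from the installed package
fx_ref <- load_reference()
fx_model <- load_structure_model(ref = fx_ref)
fx_variants <- load_variant_table()
fx_subjects <- load_subject_table()
fx_aliases <- load_insertion_aliases()
fx_markers <- load_haplogroup_table()

# substitute one base of the region sequence (local 1-based rCRS position)
with_substitution <- function(ref, pos, base) {
  s <- strsplit(region_sequence(ref), "")[[1]]
  s[pos - ref$region_start + 1] <- base
  paste(s, collapse = "")
}

# insert bases after a given rCRS position
with_insertion_after <- function(ref, pos, bases) {
  s <- strsplit(region_sequence(ref), "")[[1]]
  paste(append(s, strsplit(bases, "")[[1]], after = pos - ref$region_start + 1),
        collapse = "")
}

# a small reference over a slice of the region, usable as its own target
mini_reference <- function(ref, start, end) {
  mt_reference("mini", substr(ref$sequence, start - ref$amplicon_start + 1,
                              end - ref$amplicon_start + 1),
               region_start = start, region_end = end,
               amplicon_start = start, amplicon_end = end)
}
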