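#!/usr/bin/env Rscript
# Variant catalogue overview: load the packaged case/control catalogue and
# recompute every frequency from counts (printed percentages are never
# stored). Writes results/catalogue.tsv.
suppressMessages(library(mito12s))
dir.create("results", showWarnings = FALSE)

variants <- load_variant_table()
variants$case_percent <- percent_of(variants$case_count, 440)
variants$control_percent <- percent_of(variants$control_count, 449)
write_variant_table(variants, "results/catalogue.tsv")

cat("catalogued variants:", nrow(variants), "\n")
cat("absent in 449 controls:", sum(variants$control_count == 0), "\n")
cat("novel (not previously reported):", sum(!variants$previously_reported), "\n")
cat("1555A>G case frequency:",
    variants$case_percent[variants$name == "1555A>G"], "%\n")
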