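#!/usr/bin/env Rscript
# Secondary-structure annotation: localize every catalogued variant to stem
# or loop on the curated pair model and classify its Watson-Crick pairing
# effect. Writes results/structure.tsv.
suppressMessages(library(mito12s))
dir.create("results", showWarnings = FALSE)

ref <- load_reference()
model <- load_structure_model(ref = ref)
variants <- load_variant_table()
ann <- annotate_all(variants, model, ref)
write.table(ann$annotations, "results/structure.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, na = ".")

cat("loop:", ann$summary["loop"], " stem:", ann$summary["stem"], "\n")
cat("WC pairs created:", ann$summary["creates"],
    " abolished:", ann$summary["abolishes"], "\n")
creates <- ann$annotations$name[ann$annotations$wc_effect == "creates"]
cat("creating variants:", paste(creates, collapse = ", "), "\n")
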