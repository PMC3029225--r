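#!/usr/bin/env Rscript
# Pathogenicity classification: apply the three-criterion evaluation with
# the known-mutation and haplogroup-marker registries to the catalogue.
# Writes results/classification.tsv.
suppressMessages(library(mito12s))
dir.create("results", showWarnings = FALSE)

ref <- load_reference()
model <- load_structure_model(ref = ref)
variants <- load_variant_table()
cls <- classify_all(variants, classifier_config(), model = model, ref = ref)
write.table(cls$table, "results/classification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, na = ".")

s <- cls$summary
cat("variants:", s$n_variants,
    "| absent in controls:", s$n_absent_in_controls,
    "| control freq < 1%:", s$n_control_freq_lt1, "\n")
cat("CI >= 11/14:", s$n_ci_above_threshold,
    "| criteria 1 and 2:", s$n_criteria12, "\n")
cat("categories: known", s$known_pathogenic,
    "/ putative", s$putative_deafness_associated,
    "/ haplogroup", s$haplogroup_polymorphism,
    "/ polymorphism", s$polymorphism, "\n")
put <- cls$table$name[cls$table$category == "putative_deafness_associated"]
cat("putative deafness-associated:", paste(put, collapse = ", "), "\n")
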