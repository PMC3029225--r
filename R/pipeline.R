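.config_digest <- function(x) {
  v <- utf8ToInt(paste(deparse(x), collapse = ""))
  sprintf("%08x", sum(v * seq_along(v)) %% 2^31)
}

.write_stage <- function(df, path, seed, digest) {
  con <- file(path, "w")
  writeLines(sprintf("# mito12s %s seed=%d config=%s",
                     as.character(utils::packageVersion("mito12s")),
                     seed, digest), con)
  close(con)
  suppressWarnings(utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE,
    append = TRUE, na = "."))
  invisible(path)
}

#' Run the full 12S rRNA screening pipeline on the packaged fixtures
#'
#' Chains the stages - conservation (on a synthetic primate alignment
#' matched to the catalogue's CI targets), structure annotation,
#' three-criterion classification, and cohort statistics over the
#' fixture-matched synthetic cohort - and writes one TSV per stage plus a
#' plain-text summary. Every output carries a header with the package
#' version, the seed, and a configuration digest. Deterministic for a
#' fixed seed.
#'
#' @param out_dir output directory (created if needed)
#' @param seed RNG seed for the synthetic stages
#' @param config a `ClassifierConfig`
#' @param cohort_sequences also generate, write and re-call the planted
#'   case/control sequences (slower); otherwise cohort statistics are
#'   computed from the planted subject table
#' @return invisibly, a list of summary quantities
#' @export
run_screen <- function(out_dir, seed = 1, config = classifier_config(),
                       cohort_sequences = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- load_reference()
  variants <- load_variant_table()
  model <- load_structure_model(ref = ref)
  digest <- .config_digest(list(config, seed))

  aln <- generate_primate_alignment(
    ref, fixture_conservation_spec(variants, seed = seed))
  ci <- ci_table(aln, variants)
  .write_stage(ci, file.path(out_dir, "conservation.tsv"), seed, digest)

  ann <- annotate_all(variants, model, ref)
  .write_stage(ann$annotations, file.path(out_dir, "structure.tsv"),
               seed, digest)

  cls <- classify_all(variants, config, model = model, ref = ref)
  .write_stage(cls$table, file.path(out_dir, "classification.tsv"),
               seed, digest)

  spec <- default_cohort_spec(variants, seed = seed)
  cohort <- generate_cohort(ref, spec, sequences = cohort_sequences)
  subjects <- cohort$subjects
  .write_stage(subjects, file.path(out_dir, "cohort_subjects.tsv"),
               seed, digest)
  if (cohort_sequences) {
    write_fasta(cohort$case_seqs, file.path(out_dir, "case_sequences.fasta"))
    calls <- call_cohort(cohort$case_seqs, ref)
    .write_stage(calls, file.path(out_dir, "case_calls.tsv"), seed, digest)
  }

  classification <- stats::setNames(cls$table$category, cls$table$name)
  freq <- rbind(
    variant_frequency(subjects, "1555A>G"),
    variant_frequency(subjects, "1555A>G", subset = subjects$exposed,
                      subgroup_label = "aminoglycoside_exposed"),
    variant_frequency(subjects, "1494C>T"),
    variant_frequency(subjects, "1095T>C"),
    exposure_fraction(subjects),
    attributable_fraction(subjects, classification))
  .write_stage(freq, file.path(out_dir, "frequencies.tsv"), seed, digest)

  summary <- list(
    n_variants = cls$summary$n_variants,
    n_absent_in_controls = cls$summary$n_absent_in_controls,
    n_ci_above_threshold = cls$summary$n_ci_above_threshold,
    n_criteria12 = cls$summary$n_criteria12,
    n_creates = unname(ann$summary["creates"]),
    n_abolishes = unname(ann$summary["abolishes"]),
    putative = cls$table$name[cls$table$category ==
                                "putative_deafness_associated"],
    frequencies = freq,
    severity_exposed = severity_summary(subjects, subjects$exposed),
    severity_unexposed = severity_summary(subjects, !subjects$exposed))
  txt <- c(sprintf("# mito12s %s seed=%d config=%s",
                   as.character(utils::packageVersion("mito12s")), seed, digest),
           sprintf("variants catalogued: %d", summary$n_variants),
           sprintf("absent in controls: %d", summary$n_absent_in_controls),
           sprintf("CI >= threshold: %d", summary$n_ci_above_threshold),
           sprintf("criteria 1 and 2: %d", summary$n_criteria12),
           sprintf("WC pairs created / abolished: %d / %d",
                   summary$n_creates, summary$n_abolishes),
           sprintf("putative deafness-associated: %s",
                   paste(summary$putative, collapse = ", ")))
  writeLines(txt, file.path(out_dir, "summary.txt"))
  invisible(summary)
}
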