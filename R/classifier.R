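#' Classifier configuration
#'
#' Settings for the three-criterion pathogenicity evaluation:
#' criterion 1 - absence from the Han Chinese control panel;
#' criterion 2 - conservation at or above the species-count threshold
#' (default 11 of 14 species, i.e. CI >= 78.6%, the lattice value
#' operationalizing the published ">78%" cutoff);
#' criterion 3 - structural evidence, reported as a tier but not gating.
#' A registry of known deafness mutations takes precedence over the
#' criteria, and a haplogroup-marker registry labels lineage polymorphisms.
#'
#' @param control_panel_size control denominator (default 449)
#' @param ci_threshold_species matches-out-of-14 threshold (default 11)
#' @param known_pathogenic_registry variant names classified
#'   `known_pathogenic` unconditionally
#' @param haplogroup_markers named vector variant -> haplogroup
#' @param n_species conservation panel size (default 14)
#' @param loop_ci_species species-count floor for the `loop_high_ci`
#'   evidence tier (default 13, i.e. CI >= 92.9%)
#' @return a `ClassifierConfig` list
#' @export
classifier_config <- function(control_panel_size = 449,
                              ci_threshold_species = 11,
                              known_pathogenic_registry =
                                c("1555A>G", "1494C>T", "1095T>C"),
                              haplogroup_markers = load_haplogroup_table(),
                              n_species = 14,
                              loop_ci_species = 13) {
  stopifnot(ci_threshold_species > 0, ci_threshold_species <= n_species)
  structure(list(control_panel_size = as.integer(control_panel_size),
                 ci_threshold_species = as.integer(ci_threshold_species),
                 known_pathogenic_registry = known_pathogenic_registry,
                 haplogroup_markers = haplogroup_markers,
                 n_species = as.integer(n_species),
                 loop_ci_species = as.integer(loop_ci_species)),
            class = "ClassifierConfig")
}

.c3_tier <- function(location, effect, n_matching, config) {
  if (!is.na(location) && location == "stem" && !is.na(effect) &&
      effect != "none") "stem_wc_change"
  else if (!is.na(location) && location == "loop" &&
           n_matching >= config$loop_ci_species) "loop_high_ci"
  else "none"
}

#' Evaluate the three pathogenicity criteria for one variant record
#'
#' Criteria are computed from integer counts: criterion 1 from the control
#' carrier count, criterion 2 from the matches-out-of-14 species count
#' (recovered from the record's CI when `n_matching` is absent), criterion
#' 3 from the structure annotation when supplied.
#'
#' @param record one-row variant record (needs control_count and
#'   ci_percent or n_matching; optionally location/wc_effect from
#'   [annotate_all()])
#' @param config a `ClassifierConfig`
#' @return one-row data.frame: name, c1_absent_in_controls,
#'   c2_ci_above_threshold, c3_structural_evidence
#' @export
evaluate_criteria <- function(record, config = classifier_config()) {
  if (is.null(record$control_count) || is.na(record$control_count))
    stop("record lacks a control count", call. = FALSE)
  n_matching <- if (!is.null(record$n_matching) && !is.na(record$n_matching))
    record$n_matching
  else if (!is.null(record$ci_percent) && !is.na(record$ci_percent))
    ci_to_matches(record$ci_percent, config$n_species)
  else stop("missing CI for ", record$name, call. = FALSE)
  loc <- if ("location" %in% names(record)) record$location else NA_character_
  eff <- if ("wc_effect" %in% names(record)) record$wc_effect else NA_character_
  data.frame(name = record$name,
             c1_absent_in_controls = record$control_count == 0,
             c2_ci_above_threshold = n_matching >= config$ci_threshold_species,
             c3_structural_evidence = .c3_tier(loc, eff, n_matching, config),
             stringsAsFactors = FALSE)
}

#' Classify one variant record
#'
#' Category resolution: registry membership -> `known_pathogenic`;
#' else criteria 1 and 2 both met -> `putative_deafness_associated`;
#' else haplogroup marker -> `haplogroup_polymorphism`;
#' else `polymorphism`. Criterion 3 is carried as evidence only.
#'
#' @inheritParams evaluate_criteria
#' @return one-row data.frame with criteria flags, category and haplogroup
#' @export
classify <- function(record, config = classifier_config()) {
  cr <- evaluate_criteria(record, config)
  hap <- unname(config$haplogroup_markers[record$name])
  cr$category <-
    if (record$name %in% config$known_pathogenic_registry) "known_pathogenic"
    else if (cr$c1_absent_in_controls && cr$c2_ci_above_threshold)
      "putative_deafness_associated"
    else if (!is.na(hap)) "haplogroup_polymorphism"
    else "polymorphism"
  cr$haplogroup <- hap
  cr
}

#' Classify a variant catalogue
#'
#' Runs [classify()] over every record, optionally joining structure
#' annotations first so that criterion-3 tiers are populated, and returns
#' the annotated table with the summary counts used in the cohort report.
#'
#' @param records variant table as from [load_variant_table()]
#' @param config a `ClassifierConfig`
#' @param model optional `StructureModel` (with `ref`) to compute
#'   stem/loop evidence
#' @param ref optional `MtReference`
#' @return list with `table` (records + criteria + category) and `summary`
#'   (n_variants, n_absent_in_controls, n_control_freq_lt1,
#'   n_ci_above_threshold, n_criteria12, per-category counts)
#' @export
classify_all <- function(records, config = classifier_config(),
                         model = NULL, ref = NULL) {
  if (nrow(records) > 0 && !is.null(model) && !is.null(ref)) {
    ann <- annotate_all(records, model, ref)$annotations
    records$location <- ann$location
    records$wc_effect <- ann$wc_effect
  }
  if (nrow(records) == 0) {
    tab <- cbind(records,
                 data.frame(c1_absent_in_controls = logical(),
                            c2_ci_above_threshold = logical(),
                            c3_structural_evidence = character(),
                            category = character(),
                            haplogroup = character()))
  } else {
    cr <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
      classify(records[i, , drop = FALSE], config)))
    tab <- cbind(records, cr[setdiff(names(cr), "name")])
    rownames(tab) <- NULL
  }
  n_lt1 <- sum(tab$control_count > 0 &
                 100 * tab$control_count / config$control_panel_size < 1)
  cats <- table(factor(tab$category,
                       levels = c("known_pathogenic",
                                  "putative_deafness_associated",
                                  "haplogroup_polymorphism", "polymorphism")))
  list(table = tab,
       summary = c(list(n_variants = nrow(tab),
                        n_absent_in_controls = sum(tab$c1_absent_in_controls),
                        n_control_freq_lt1 = as.integer(n_lt1),
                        n_ci_above_threshold = sum(tab$c2_ci_above_threshold),
                        n_criteria12 = sum(tab$c1_absent_in_controls &
                                             tab$c2_ci_above_threshold)),
                   as.list(stats::setNames(as.integer(cats), names(cats)))))
}
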