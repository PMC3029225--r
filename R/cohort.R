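#' Pure-tone average
#'
#' Mean audiometric threshold over the five test frequencies
#' 500/1000/2000/4000/8000 Hz.
#'
#' @param thresholds_db exactly five non-negative thresholds in dB
#' @return PTA in dB
#' @export
compute_pta <- function(thresholds_db) {
  if (length(thresholds_db) != 5)
    stop("PTA requires exactly five thresholds", call. = FALSE)
  if (any(thresholds_db < 0)) stop("negative threshold", call. = FALSE)
  mean(thresholds_db)
}

#' Five-grade severity of hearing impairment
#'
#' Grades a PTA on the clinical scale: normal <26 dB, mild 26-40, moderate
#' 41-70, severe 71-90, profound >90 (boundaries inclusive as printed).
#' Grading follows the integer boundaries, so fractional PTAs in the open
#' gaps (e.g. 40.5) fall into the higher grade.
#'
#' @param pta_db PTA value(s) in dB, >= 0
#' @return character grade(s)
#' @export
grade_severity <- function(pta_db) {
  stopifnot(all(pta_db >= 0))
  cut(pta_db, breaks = c(-Inf, 25, 40, 70, 90, Inf),
      labels = SEVERITY_LEVELS) |> as.character()
}

#' The five severity grades, mildest first
#' @return character vector of grade labels
#' @export
severity_levels <- function() SEVERITY_LEVELS

.worse_pta <- function(cohort) pmax(cohort$pta_right_db, cohort$pta_left_db)

#' Compare worse-ear grading with recorded severity labels
#'
#' Subject-level severity is defined as the grade of the worse (higher-PTA)
#' ear. Returns the computed grades alongside the recorded labels and the
#' ids of discordant subjects, which on the packaged table are boundary
#' sitters (PTA exactly on a grade edge) rather than silent errors.
#'
#' @param cohort subject table (needs pta_right_db, pta_left_db, severity)
#' @return list with `computed`, `recorded`, `n_agree`, `discordant` ids
#' @export
grade_concordance <- function(cohort) {
  computed <- grade_severity(.worse_pta(cohort))
  recorded <- tolower(cohort$severity)
  list(computed = computed, recorded = recorded,
       n_agree = sum(computed == recorded),
       discordant = cohort$subject_id[computed != recorded])
}

.subject_variants <- function(cohort) {
  v <- cohort[[if ("variants" %in% names(cohort)) "variants" else "variant"]]
  v[is.na(v)] <- ""
  strsplit(v, ";", fixed = TRUE)
}

.apply_subset <- function(cohort, subset) {
  if (is.null(subset)) return(cohort)
  keep <- if (is.function(subset)) subset(cohort) else subset
  cohort[keep, , drop = FALSE]
}

.freq_result <- function(variant, subgroup, carriers, denominator) {
  if (denominator == 0) stop("empty subgroup", call. = FALSE)
  data.frame(variant = variant, subgroup = subgroup,
             carrier_count = as.integer(carriers),
             denominator = as.integer(denominator),
             percent = percent_of(carriers, denominator),
             stringsAsFactors = FALSE)
}

#' Carrier frequency of a variant in a (sub)cohort
#'
#' Counts subjects carrying the named variant and recomputes the percent
#' from counts (one decimal; two decimals below 1%).
#'
#' @param cohort subject table with a `variant`/`variants` column
#'   (semicolon-separated names)
#' @param variant_name variant to count
#' @param subset optional logical vector or predicate function selecting
#'   the subgroup
#' @param subgroup_label label stored in the result
#' @return one-row frequency data.frame
#' @export
variant_frequency <- function(cohort, variant_name, subset = NULL,
                              subgroup_label = if (is.null(subset)) "all" else "subgroup") {
  sub <- .apply_subset(cohort, subset)
  carriers <- sum(vapply(.subject_variants(sub),
                         function(v) variant_name %in% v, logical(1)))
  .freq_result(variant_name, subgroup_label, carriers, nrow(sub))
}

#' Aminoglycoside exposure fraction of a cohort
#'
#' @param cohort subject table with logical `exposed`
#' @return one-row frequency data.frame
#' @export
exposure_fraction <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  .freq_result("aminoglycoside_exposure", "all", sum(cohort$exposed),
               nrow(cohort))
}

#' Fraction of exposed subjects carrying a pathogenic-class variant
#'
#' Among aminoglycoside-exposed subjects, the fraction carrying at least
#' one variant whose classifier category is in `pathogenic_categories`.
#' This is the cohort's aminoglycoside-attributable fraction for the
#' screened gene; the exact fraction is reported, not a rounded headline.
#'
#' @param cohort subject table with `exposed` and a variants column
#' @param classification named vector: variant name -> category
#' @param pathogenic_categories category labels counted as pathogenic
#' @return one-row frequency data.frame
#' @export
attributable_fraction <- function(cohort, classification,
                                  pathogenic_categories =
                                    c("known_pathogenic",
                                      "putative_deafness_associated")) {
  exposed <- cohort[cohort$exposed, , drop = FALSE]
  if (nrow(exposed) == 0) stop("empty subgroup: no exposed subjects", call. = FALSE)
  carried <- .subject_variants(exposed)
  all_names <- unique(unlist(carried))
  all_names <- all_names[nzchar(all_names)]
  missing <- setdiff(all_names, names(classification))
  if (length(missing) > 0)
    stop("unclassified variant encountered: ", missing[1], call. = FALSE)
  hit <- vapply(carried, function(v)
    any(classification[v[nzchar(v)]] %in% pathogenic_categories), logical(1))
  .freq_result("pathogenic_12S_variant", "aminoglycoside_exposed",
               sum(hit), nrow(exposed))
}

#' Severity-grade histogram of a (sub)cohort
#'
#' @param cohort subject table with a `severity` column
#' @param subset optional logical vector or predicate function
#' @return named integer vector over the five grades (sums to the subgroup
#'   size)
#' @export
severity_summary <- function(cohort, subset = NULL) {
  sub <- .apply_subset(cohort, subset)
  if (nrow(sub) == 0) stop("empty subgroup", call. = FALSE)
  tab <- table(factor(tolower(sub$severity), levels = SEVERITY_LEVELS))
  stats::setNames(as.integer(tab), SEVERITY_LEVELS)
}
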