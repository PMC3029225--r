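#' @importFrom Biostrings readDNAStringSet DNAString DNAStringSet
#'   pairwiseAlignment alignedPattern alignedSubject reverseComplement
#'   writeXStringSet
NULL

SEVERITY_LEVELS <- c("normal", "mild", "moderate", "severe", "profound")

#' Reference sequence with rCRS coordinates
#'
#' Container for the mitochondrial reference used throughout the pipeline.
#' All coordinates are 1-based inclusive rCRS positions. The packaged
#' default is a synthetic rCRS-like amplicon spanning positions 618-2007
#' with the 12S rRNA analysis region at 648-1601.
#'
#' @param name sequence label
#' @param sequence nucleotide string covering the amplicon
#' @param region_start,region_end rCRS bounds of the analyzed rRNA region
#' @param amplicon_start,amplicon_end rCRS bounds of the sequenced fragment
#' @return an object of class `MtReference`
#' @export
mt_reference <- function(name, sequence, region_start, region_end,
                         amplicon_start, amplicon_end) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("alphabet violation: reference contains characters outside A/C/G/T/N",
         call. = FALSE)
  if (nchar(sequence) != amplicon_end - amplicon_start + 1)
    stop("sequence length does not match amplicon coordinates", call. = FALSE)
  if (!(amplicon_start <= region_start && region_end <= amplicon_end))
    stop("region must be nested inside the amplicon", call. = FALSE)
  structure(list(name = name, sequence = sequence,
                 region_start = as.integer(region_start),
                 region_end = as.integer(region_end),
                 amplicon_start = as.integer(amplicon_start),
                 amplicon_end = as.integer(amplicon_end)),
            class = "MtReference")
}

#' @export
print.MtReference <- function(x, ...) {
  cat(sprintf("MtReference '%s': amplicon %d-%d, region %d-%d (%d nt)\n",
              x$name, x$amplicon_start, x$amplicon_end,
              x$region_start, x$region_end,
              x$region_end - x$region_start + 1))
  invisible(x)
}

#' Nucleotides of the analyzed region
#'
#' @param ref an `MtReference`
#' @return the region as a plain character string
#' @export
region_sequence <- function(ref) {
  substr(ref$sequence, ref$region_start - ref$amplicon_start + 1,
         ref$region_end - ref$amplicon_start + 1)
}

#' Reference base at an rCRS position
#'
#' @param ref an `MtReference`
#' @param pos rCRS position(s) inside the amplicon
#' @return character vector of single bases
#' @export
ref_base <- function(ref, pos) {
  if (any(pos < ref$amplicon_start | pos > ref$amplicon_end))
    stop("position outside amplicon", call. = FALSE)
  substring(ref$sequence, pos - ref$amplicon_start + 1,
            pos - ref$amplicon_start + 1)
}

#' Read the flat key=value region configuration
#'
#' @param path configuration file; defaults to the packaged one
#' @return named list with integer bounds and the human row id
#' @export
load_region_config <- function(path = mito12s_extdata("region_config.txt")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- stats::setNames(lapply(kv, function(x) trimws(x[2])),
                         vapply(kv, function(x) trimws(x[1]), ""))
  for (k in c("region_start", "region_end", "amplicon_start", "amplicon_end"))
    cfg[[k]] <- as.integer(cfg[[k]])
  cfg
}

#' Load the reference FASTA
#'
#' @param path single-record FASTA; defaults to the packaged synthetic
#'   rCRS-like amplicon
#' @param config region configuration as from [load_region_config()]
#' @return an `MtReference`
#' @export
load_reference <- function(path = mito12s_extdata("rnr1_reference_synthetic.fasta"),
                           config = load_region_config()) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty record: no sequences in ", path, call. = FALSE)
  if (length(ss) > 1) stop("multiple records in reference FASTA", call. = FALSE)
  mt_reference(name = sub("\\s.*", "", names(ss)[1]),
               sequence = as.character(ss[[1]]),
               region_start = config$region_start,
               region_end = config$region_end,
               amplicon_start = config$amplicon_start,
               amplicon_end = config$amplicon_end)
}

#' Load the 41-variant case/control catalogue
#'
#' Reads the packaged transcription of the cohort variant table: one row per
#' distinct 12S rRNA variant with its conservation index, Watson-Crick
#' arrow annotation, and case/control carrier counts. Printed percentages
#' are never stored; all frequencies are recomputed from counts.
#'
#' @param path TSV file; defaults to the packaged fixture
#' @return data.frame with one row per variant record
#' @export
load_variant_table <- function(path = mito12s_extdata("variant_table2.tsv")) {
  need <- c("position", "ref", "alt", "kind", "name", "ci_percent",
            "wc_arrow", "wc_pair", "previously_reported",
            "case_count", "control_count")
  if (file.exists(path) && file.size(path) == 0) {
    empty <- data.frame(matrix(nrow = 0, ncol = length(need)))
    names(empty) <- need
    return(empty)
  }
  df <- read_tsv_strict(path)
  if (!all(need %in% names(df)))
    stop("malformed variant table: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df <- df[need]
  df$position <- as.integer(df$position)
  df$case_count <- as.integer(df$case_count)
  df$control_count <- as.integer(df$control_count)
  if (any(is.na(df$position)) || any(is.na(df$case_count)) ||
      any(is.na(df$control_count)))
    stop("malformed row: non-numeric position or count", call. = FALSE)
  if (any(df$case_count < 0) || any(df$control_count < 0))
    stop("malformed row: negative count", call. = FALSE)
  key <- paste(df$position, ifelse(is.na(df$ref), "-", df$ref),
               ifelse(is.na(df$alt), "-", df$alt), df$kind)
  if (anyDuplicated(key))
    stop("duplicate (position, replacement) pair in variant table", call. = FALSE)
  df$previously_reported <- yesno_to_flag(df$previously_reported)
  df
}

#' Write a variant catalogue back to TSV
#' @param df table as returned by [load_variant_table()]
#' @param path output file
#' @export
write_variant_table <- function(df, path) write_tsv_plain(df, path)

#' Load the curated rRNA secondary-structure pair model
#'
#' The model is data, not computation: a curated table of apposed stem
#' position pairs, each flagged as Watson-Crick paired or apposed-but-
#' unpaired in the wild type (the 1494/1555 A-site case). Every position
#' not covered by a pair is loop.
#'
#' @param path TSV with columns pos5, pos3, wild_paired
#' @param ref optional `MtReference`; when given, positions are checked to
#'   lie inside the region and the wild-pairing flags are checked against
#'   the reference bases
#' @return an object of class `StructureModel`
#' @export
load_structure_model <- function(path = mito12s_extdata("structure_pairs.tsv"),
                                 ref = NULL) {
  df <- read_tsv_strict(path)
  if (!all(c("pos5", "pos3", "wild_paired") %in% names(df)))
    stop("malformed structure model: need pos5, pos3, wild_paired", call. = FALSE)
  df$pos5 <- as.integer(df$pos5); df$pos3 <- as.integer(df$pos3)
  df$wild_paired <- yesno_to_flag(df$wild_paired)
  structure_model(df, ref = ref)
}

#' Construct and validate a structure model from a pair table
#' @param pairs data.frame with pos5, pos3, wild_paired
#' @param ref optional `MtReference` for consistency checks
#' @return an object of class `StructureModel`
#' @export
structure_model <- function(pairs, ref = NULL) {
  if (any(pairs$pos5 >= pairs$pos3))
    stop("structure model: pos5 must be < pos3 in every pair", call. = FALSE)
  all_pos <- c(pairs$pos5, pairs$pos3)
  if (anyDuplicated(all_pos))
    stop("overlapping pairs: a position appears in more than one pair",
         call. = FALSE)
  if (!is.null(ref)) {
    if (any(all_pos < ref$region_start | all_pos > ref$region_end))
      stop("structure model: position outside region", call. = FALSE)
    wc <- is_wc_pair(ref_base(ref, pairs$pos5), ref_base(ref, pairs$pos3))
    if (any(wc != pairs$wild_paired))
      stop("structure model: wild_paired flag disagrees with reference bases at pair (",
           pairs$pos5[which(wc != pairs$wild_paired)[1]], ")", call. = FALSE)
  }
  structure(list(pairs = pairs), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel: %d apposed pairs (%d WC-paired in wild type)\n",
              nrow(x$pairs), sum(x$pairs$wild_paired)))
  invisible(x)
}

#' Load the clinical subject table
#'
#' One row per hearing-impaired carrier of a definite or putative 12S rRNA
#' mutation: sex, audiometric configuration, onset age, per-ear pure-tone
#' average, aminoglycoside use and the printed severity grade.
#'
#' @param path TSV file; defaults to the packaged 44-subject fixture
#' @return data.frame with a logical `exposed` column parsed from drug use
#' @export
load_subject_table <- function(path = mito12s_extdata("subject_table3.tsv")) {
  df <- read_tsv_strict(path)
  need <- c("variant", "gjb2", "subject_id", "sex", "configuration",
            "onset_age_years", "pta_right_db", "pta_left_db",
            "drug_use", "severity")
  if (!all(need %in% names(df)))
    stop("malformed subject table: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df <- df[need]
  df$pta_right_db <- suppressWarnings(as.numeric(df$pta_right_db))
  df$pta_left_db <- suppressWarnings(as.numeric(df$pta_left_db))
  if (any(is.na(df$pta_right_db)) || any(is.na(df$pta_left_db)))
    stop("non-numeric PTA value in subject table", call. = FALSE)
  sev <- tolower(df$severity)
  if (any(!sev %in% SEVERITY_LEVELS))
    stop("unknown severity label: ", df$severity[!sev %in% SEVERITY_LEVELS][1],
         call. = FALSE)
  df$severity <- sev
  df$exposed <- yesno_to_flag(df$drug_use)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject ids in subject table", call. = FALSE)
  df
}

#' Write a subject table back to TSV
#' @param df table as returned by [load_subject_table()]
#' @param path output file
#' @export
write_subject_table <- function(df, path) {
  write_tsv_plain(df[setdiff(names(df), "exposed")], path)
}

#' Load the haplogroup marker registry
#'
#' Maps lineage-defining mtDNA variants (treated as neutral or adaptive
#' polymorphisms) to their haplogroup labels. The packaged default carries
#' the 13 marker assignments across 8 Han Chinese haplogroups used by the
#' classifier.
#'
#' @param path TSV with columns variant, haplogroup
#' @return named character vector: variant name -> haplogroup
#' @export
load_haplogroup_table <- function(path = mito12s_extdata("haplogroup_markers.tsv")) {
  df <- read_tsv_strict(path)
  if (!all(c("variant", "haplogroup") %in% names(df)))
    stop("malformed haplogroup table", call. = FALSE)
  if (anyDuplicated(df$variant))
    stop("duplicate variant in haplogroup table", call. = FALSE)
  stats::setNames(df$haplogroup, df$variant)
}

#' Load the legacy insertion-name alias table
#'
#' Indels are left-normalized to the 5'-most position; this table maps the
#' canonical left-normalized names to the legacy names used in the field's
#' reports (e.g. the packaged reference's canonical 956insC to the printed
#' 961insC).
#'
#' @param path TSV with columns canonical, legacy
#' @return named character vector: canonical -> legacy
#' @export
load_insertion_aliases <- function(path = mito12s_extdata("insertion_aliases.tsv")) {
  df <- read_tsv_strict(path)
  stats::setNames(df$legacy, df$canonical)
}

#' Multi-species alignment with rCRS column mapping
#'
#' @param species_ids row labels (the human row among them)
#' @param rows aligned sequences, equal length, gap symbol `-` allowed
#' @param human_id label of the human reference row
#' @param region_start rCRS position of the first human (non-gap) column
#' @param ref optional `MtReference`; when given, the degapped human row is
#'   checked to equal the region sequence
#' @return an object of class `PrimateAlignment`
#' @export
primate_alignment <- function(species_ids, rows, human_id, region_start,
                              ref = NULL) {
  if (length(rows) != length(species_ids))
    stop("species_ids and rows differ in length", call. = FALSE)
  if (length(unique(nchar(rows))) != 1)
    stop("alignment rows have unequal length", call. = FALSE)
  hi <- match(human_id, species_ids)
  if (is.na(hi)) stop("human row '", human_id, "' not found", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  rownames(mat) <- species_ids
  human <- mat[hi, ]
  positions <- rep(NA_integer_, ncol(mat))
  nongap <- human != "-"
  positions[nongap] <- region_start + seq_len(sum(nongap)) - 1L
  if (!is.null(ref)) {
    if (paste(human[nongap], collapse = "") != region_sequence(ref))
      stop("human alignment row does not match the reference region",
           call. = FALSE)
  }
  structure(list(species = species_ids, mat = mat, human_row = hi,
                 positions = positions, region_start = as.integer(region_start)),
            class = "PrimateAlignment")
}

#' @export
print.PrimateAlignment <- function(x, ...) {
  cat(sprintf("PrimateAlignment: %d species x %d columns (human row: %s)\n",
              nrow(x$mat), ncol(x$mat), x$species[x$human_row]))
  invisible(x)
}

#' Load an aligned multi-FASTA primate alignment
#'
#' @param path aligned multi-FASTA (14 rows for the packaged analysis)
#' @param human_id id of the human row
#' @param region_start rCRS position of the first human base
#' @param ref optional `MtReference` for the human-row consistency check
#' @return a `PrimateAlignment`
#' @export
load_primate_alignment <- function(path, human_id = "Homo_sapiens",
                                   region_start = 648L, ref = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  primate_alignment(sub("\\s.*", "", names(ss)), as.character(ss),
                    human_id, region_start, ref = ref)
}

#' Write a primate alignment as aligned multi-FASTA
#' @param aln a `PrimateAlignment`
#' @param path output FASTA path
#' @export
write_primate_alignment <- function(aln, path) {
  rows <- apply(aln$mat, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", aln$species), rows)), path)
  invisible(path)
}
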