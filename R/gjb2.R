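#' Load the GJB2 coding reference
#'
#' The packaged default is a synthetic stand-in coding sequence of the
#' correct length (678 nt) carrying the documented bases at the screened
#' positions; a true GJB2 CDS FASTA can be substituted via `path` without
#' code change. Coordinates are cDNA positions, 1 = first base of the
#' start codon.
#'
#' @param path single-record FASTA
#' @return an `MtReference` spanning the CDS in cDNA coordinates
#' @export
load_gjb2_reference <- function(path = mito12s_extdata("gjb2_cds_synthetic.fasta")) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty record in ", path, call. = FALSE)
  if (length(ss) > 1) stop("multiple records in GJB2 reference", call. = FALSE)
  n <- Biostrings::nchar(ss)[1]
  mt_reference(sub("\\s.*", "", names(ss)[1]), as.character(ss[[1]]),
               region_start = 1, region_end = n,
               amplicon_start = 1, amplicon_end = n)
}

#' Screen one GJB2 allele for coding-region mutations
#'
#' Globally aligns a per-allele coding sequence against the wild type and
#' extracts left-normalized variants in cDNA coordinates, named in the
#' field's style (235delC, 299delAT).
#'
#' @param allele_seq nucleotide string covering the full coding region
#' @param ref_cds GJB2 reference as from [load_gjb2_reference()]
#' @return data.frame of variants (possibly empty)
#' @export
screen_gjb2 <- function(allele_seq, ref_cds) {
  n <- ref_cds$region_end - ref_cds$region_start + 1
  if (nchar(allele_seq) < 0.9 * n)
    stop("incomplete coverage of the GJB2 coding region", call. = FALSE)
  aln <- align_to_reference(allele_seq, ref_cds)
  extract_variants(aln, ref_cds, aliases = NULL)
}

#' Interpret a two-allele GJB2 screen
#'
#' @param a1,a2 variant name vectors (or screen data.frames) for the two
#'   alleles
#' @return list: allele1, allele2, `interpretation` (none / monoallelic /
#'   biallelic) and a compound `label` such as "235delC/299delAT"
#' @export
interpret_genotype <- function(a1, a2) {
  nm <- function(x) if (is.data.frame(x)) x$name else as.character(x)
  a1 <- nm(a1); a2 <- nm(a2)
  interp <- if (length(a1) > 0 && length(a2) > 0) "biallelic"
            else if (length(a1) > 0 || length(a2) > 0) "monoallelic"
            else "none"
  lab <- if (interp == "none") "." else
    paste(c(paste(a1, collapse = "+"), paste(a2, collapse = "+"))[
      c(length(a1) > 0, length(a2) > 0)], collapse = "/")
  list(allele1 = a1, allele2 = a2, interpretation = interp, label = lab)
}

#' Screen a cohort of GJB2 alleles
#'
#' Input ids follow the `subject|allele` convention (allele 1 or 2). A
#' subject supplying a single consensus sequence is screened as one allele
#' and flagged phase-unknown with a warning.
#'
#' @param sequences named character vector or `DNAStringSet`; names
#'   "SUBJ|1", "SUBJ|2"
#' @param ref_cds GJB2 reference
#' @return data.frame (subject_id, allele1, allele2, interpretation,
#'   label); the number of subjects with any mutation is in attribute
#'   `n_mutant`
#' @export
screen_cohort_gjb2 <- function(sequences, ref_cds) {
  if (length(sequences) == 0) stop("empty input: no alleles", call. = FALSE)
  ids <- names(sequences)
  seqs <- stats::setNames(as.character(sequences), ids)
  if (is.null(ids)) stop("alleles must be named subject|allele", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate allele ids", call. = FALSE)
  subj <- sub("\\|.*$", "", ids)
  allele <- ifelse(grepl("\\|", ids), sub("^.*\\|", "", ids), "1")
  refseq <- region_sequence(ref_cds)
  out <- lapply(unique(subj), function(s) {
    sel <- which(subj == s)
    if (length(sel) == 1)
      warning("subject ", s, " supplied a single consensus sequence; ",
              "screened as one allele, phase unknown", call. = FALSE)
    if (length(sel) > 2) stop("more than two alleles for ", s, call. = FALSE)
    calls <- lapply(seqs[sel][order(allele[sel])], function(x)
      if (x == refseq) character() else screen_gjb2(x, ref_cds)$name)
    g <- interpret_genotype(calls[[1]],
                            if (length(calls) > 1) calls[[2]] else character())
    data.frame(subject_id = s,
               allele1 = if (length(g$allele1)) paste(g$allele1, collapse = "+") else ".",
               allele2 = if (length(g$allele2)) paste(g$allele2, collapse = "+") else ".",
               interpretation = g$interpretation, label = g$label,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "n_mutant") <- sum(res$interpretation != "none")
  res
}
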