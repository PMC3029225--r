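#' Construct a variant
#'
#' A single homoplasmic nucleotide change in 1-based reference coordinates.
#' Substitutions carry one reference and one alternate base; insertions are
#' anchored to the reference base after which the bases are inserted
#' (empty `ref`); deletions carry the deleted bases starting at `position`
#' (empty `alt`).
#'
#' @param position 1-based reference position (anchor base for insertions)
#' @param ref reference base(s); "" for a pure insertion
#' @param alt alternate base(s); "" for a pure deletion
#' @return one-row data.frame with position, ref, alt, kind, name
#' @export
variant <- function(position, ref = "", alt = "") {
  ref <- toupper(ref); alt <- toupper(alt)
  kind <- if (nchar(ref) == 1 && nchar(alt) == 1) "substitution"
          else if (nchar(ref) == 0 && nchar(alt) > 0) "insertion"
          else if (nchar(alt) == 0 && nchar(ref) > 0) "deletion"
          else stop("unsupported variant shape (MNVs are out of scope)",
                    call. = FALSE)
  if (kind == "substitution" && ref == alt)
    stop("substitution requires ref != alt", call. = FALSE)
  data.frame(position = as.integer(position), ref = ref, alt = alt,
             kind = kind,
             name = name_variant(position, ref, alt, kind),
             stringsAsFactors = FALSE)
}

#' Canonical variant name
#'
#' Substitutions render as `1555A>G`, insertions as `961insC`, deletions as
#' `235delC`. An alias map (canonical -> legacy) may substitute the printed
#' legacy name for left-normalized indels.
#'
#' @param position,ref,alt,kind variant fields (see [variant()])
#' @param aliases optional named character vector of legacy names
#' @return character name(s)
#' @export
name_variant <- function(position, ref, alt, kind, aliases = NULL) {
  nm <- ifelse(kind == "substitution", paste0(position, ref, ">", alt),
        ifelse(kind == "insertion", paste0(position, "ins", alt),
               paste0(position, "del", ref)))
  if (!is.null(aliases)) {
    hit <- !is.na(match(nm, names(aliases)))
    nm[hit] <- aliases[nm[hit]]
  }
  nm
}

#' Parse a variant name back into its fields
#'
#' Accepts the canonical spellings produced by [name_variant()] plus legacy
#' aliases and case-insensitive `Del`/`Ins`. For insertions and deletions
#' named by a legacy alias the canonical (left-normalized) coordinates are
#' restored first.
#'
#' @param name character vector of variant names
#' @param aliases alias map as in [name_variant()] (legacy names resolved
#'   through it)
#' @param ref optional `MtReference` used to recover deleted bases when a
#'   deletion is spelled without them
#' @return data.frame with position, ref, alt, kind, name
#' @export
parse_variant_name <- function(name, aliases = NULL, ref = NULL) {
  out <- lapply(name, function(nm0) {
    nm <- nm0
    if (!is.null(aliases)) {
      rev_hit <- match(nm, aliases)
      if (!is.na(rev_hit)) nm <- names(aliases)[rev_hit]
    }
    if (grepl("^[0-9]+[ACGT]>[ACGT]$", nm)) {
      pos <- as.integer(sub("^([0-9]+).*", "\\1", nm))
      v <- variant(pos, sub("^[0-9]+([ACGT])>.*", "\\1", nm),
                   sub(".*>([ACGT])$", "\\1", nm))
    } else if (grepl("^[0-9]+ins[ACGT]+$", nm, ignore.case = TRUE)) {
      pos <- as.integer(sub("^([0-9]+).*", "\\1", nm))
      v <- variant(pos, "", sub("^[0-9]+ins", "", nm, ignore.case = TRUE))
    } else if (grepl("^[0-9]+del[ACGT]+$", nm, ignore.case = TRUE)) {
      pos <- as.integer(sub("^([0-9]+).*", "\\1", nm))
      v <- variant(pos, sub("^[0-9]+del", "", nm, ignore.case = TRUE), "")
    } else stop("unparseable variant name: ", nm0, call. = FALSE)
    v$name <- name_variant(v$position, v$ref, v$alt, v$kind, aliases)
    v
  })
  do.call(rbind, out)
}

.align_matrix <- local({
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(bases, bases))
  diag(m) <- 1
  m["N", ] <- 0; m[, "N"] <- 0
  m
})

.gapped_identity <- function(a, b) {
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

#' Globally align a subject amplicon to the reference region
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -4,
#' gap extend -1) of a forward-orientation subject sequence against the
#' reference region. Sequences whose length deviates from the region by
#' more than `length_tol`, or whose aligned identity falls below
#' `identity_floor`, are rejected; reverse-complement input is detected and
#' rejected rather than miscalled.
#'
#' @param subject_seq nucleotide string (A/C/G/T/N)
#' @param ref an `MtReference`
#' @param length_tol allowed relative length deviation (default 0.1)
#' @param identity_floor minimum aligned identity (default 0.9)
#' @return list with gapped `pattern` (subject), gapped `subject` (reference
#'   region), `score` and `identity`
#' @export
align_to_reference <- function(subject_seq, ref, length_tol = 0.1,
                               identity_floor = 0.9) {
  subject_seq <- toupper(subject_seq)
  if (grepl("[^ACGTN]", subject_seq))
    stop("alphabet violation in subject sequence", call. = FALSE)
  refseq <- region_sequence(ref)
  n <- nchar(refseq)
  if (abs(nchar(subject_seq) - n) > length_tol * n)
    stop("unalignable: subject length outside tolerance", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    subject_seq, refseq, type = "global",
    substitutionMatrix = .align_matrix, gapOpening = 4, gapExtension = 1)
  sub_g <- as.character(Biostrings::alignedPattern(pa))
  ref_g <- as.character(Biostrings::alignedSubject(pa))
  identity <- .gapped_identity(sub_g, ref_g)
  if (identity < identity_floor) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(subject_seq)))
    pa_rc <- Biostrings::pairwiseAlignment(
      rc, refseq, type = "global",
      substitutionMatrix = .align_matrix, gapOpening = 4, gapExtension = 1)
    rc_id <- .gapped_identity(as.character(Biostrings::alignedPattern(pa_rc)),
                              as.character(Biostrings::alignedSubject(pa_rc)))
    if (rc_id >= identity_floor)
      stop("reverse-complement input detected; supply forward orientation",
           call. = FALSE)
    stop("unalignable: identity ", round(100 * identity, 1),
         "% below floor", call. = FALSE)
  }
  list(pattern = sub_g, subject = ref_g,
       score = Biostrings::score(pa), identity = identity)
}

# left-normalize an indel against the reference string (1-based local coords)
# ins: bases inserted after local position p; del: bases ref[s..e] removed
.normalize_ins <- function(refchars, p, bases) {
  b <- strsplit(bases, "")[[1]]
  while (p >= 1 && refchars[p] == b[length(b)]) {
    b <- c(b[length(b)], b[-length(b)])
    p <- p - 1
  }
  list(p = p, bases = paste(b, collapse = ""))
}

.normalize_del <- function(refchars, s, e) {
  while (s > 1 && refchars[s - 1] == refchars[e]) { s <- s - 1; e <- e - 1 }
  list(s = s, e = e)
}

#' Extract variants from a pairwise alignment
#'
#' Walks the aligned columns, maps them to rCRS positions, and emits
#' substitutions and left-normalized insertions/deletions. Columns where
#' either base is N yield a no-call at that position (returned in the
#' `no_calls` attribute), never a variant. Every call is homoplasmic by
#' assumption.
#'
#' @param aln alignment as returned by [align_to_reference()]
#' @param ref an `MtReference`
#' @param aliases legacy-name alias map (default: packaged table)
#' @return data.frame of variants sorted by position, with an integer
#'   `no_calls` attribute of rCRS positions masked by N
#' @export
extract_variants <- function(aln, ref, aliases = load_insertion_aliases()) {
  sub_c <- strsplit(aln$pattern, "")[[1]]
  ref_c <- strsplit(aln$subject, "")[[1]]
  refchars <- strsplit(region_sequence(ref), "")[[1]]
  offset <- ref$region_start - 1L

  vars <- list(); no_calls <- integer()
  i <- 1L; rp <- 0L  # rp = local reference position of last consumed ref base
  while (i <= length(ref_c)) {
    if (ref_c[i] != "-" && sub_c[i] != "-") {
      rp <- rp + 1L
      if (ref_c[i] != sub_c[i]) {
        if (ref_c[i] == "N" || sub_c[i] == "N") no_calls <- c(no_calls, offset + rp)
        else vars[[length(vars) + 1]] <-
          list(kind = "substitution", p = rp, ref = ref_c[i], alt = sub_c[i])
      }
      i <- i + 1L
    } else if (ref_c[i] == "-") {          # insertion in subject
      j <- i
      while (j <= length(ref_c) && ref_c[j] == "-") j <- j + 1L
      ins <- paste(sub_c[i:(j - 1)], collapse = "")
      if (grepl("N", ins)) no_calls <- c(no_calls, offset + rp)
      else {
        nrm <- .normalize_ins(refchars, rp, ins)
        vars[[length(vars) + 1]] <-
          list(kind = "insertion", p = nrm$p, ref = "", alt = nrm$bases)
      }
      i <- j
    } else {                               # deletion in subject
      j <- i
      while (j <= length(ref_c) && sub_c[j] == "-" && ref_c[j] != "-") j <- j + 1L
      s <- rp + 1L; e <- rp + (j - i)
      nrm <- .normalize_del(refchars, s, e)
      vars[[length(vars) + 1]] <-
        list(kind = "deletion", p = nrm$s,
             ref = paste(refchars[nrm$s:nrm$e], collapse = ""), alt = "")
      rp <- e
      i <- j
    }
  }
  if (length(vars) == 0) {
    out <- data.frame(position = integer(), ref = character(),
                      alt = character(), kind = character(),
                      name = character(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, lapply(vars, function(v) {
      pos <- offset + v$p
      data.frame(position = pos, ref = v$ref, alt = v$alt, kind = v$kind,
                 name = name_variant(pos, v$ref, v$alt, v$kind, aliases),
                 stringsAsFactors = FALSE)
    }))
    out <- out[order(out$position, out$kind), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "no_calls") <- sort(unique(no_calls))
  out
}

#' Call variants across a cohort of sequences
#'
#' Aligns every subject amplicon to the reference region and emits one call
#' table keyed by subject id. Sequences identical to the reference region
#' short-circuit the alignment.
#'
#' @param sequences named character vector or `DNAStringSet` of subject
#'   sequences (names = subject ids)
#' @param ref an `MtReference`
#' @param aliases legacy-name alias map
#' @return data.frame (subject_id, name, position, ref, alt, kind); the
#'   aggregate per-variant carrier counts are available via
#'   [aggregate_calls()]
#' @export
call_cohort <- function(sequences, ref, aliases = load_insertion_aliases()) {
  if (length(sequences) == 0) stop("empty input: no sequences", call. = FALSE)
  ids <- names(sequences)
  seqs <- stats::setNames(as.character(sequences), ids)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must be named by subject id", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate subject ids", call. = FALSE)
  refseq <- region_sequence(ref)
  rows <- lapply(seq_along(seqs), function(k) {
    if (seqs[[k]] == refseq) return(NULL)
    v <- extract_variants(align_to_reference(seqs[[k]], ref), ref, aliases)
    if (nrow(v) == 0) return(NULL)
    cbind(subject_id = ids[k], v)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject_id = character(), name = character(),
                      position = integer(), ref = character(),
                      alt = character(), kind = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[, c("subject_id", "name", "position", "ref", "alt", "kind")]
}

#' Aggregate per-variant carrier counts from a call table
#' @param calls call table from [call_cohort()]
#' @return named integer vector: variant name -> number of carriers
#' @export
aggregate_calls <- function(calls) {
  if (nrow(calls) == 0) return(stats::setNames(integer(), character()))
  tab <- table(calls$name[!duplicated(paste(calls$subject_id, calls$name))])
  stats::setNames(as.integer(tab), names(tab))
}
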