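#' Classic Watson-Crick pairing test
#'
#' TRUE iff the two bases form an A-U/A-T or G-C pair. Wobble (G-U) is
#' excluded: only classic WC pairs count for the stem bookkeeping.
#'
#' @param b1,b2 single nucleotides (A/C/G/T/U, vectorized)
#' @return logical vector
#' @export
is_wc_pair <- function(b1, b2) {
  b1 <- toupper(b1); b2 <- toupper(b2)
  b1[b1 == "U"] <- "T"; b2[b2 == "U"] <- "T"
  if (any(!c(b1, b2) %in% c("A", "C", "G", "T")))
    stop("non-nucleotide input to is_wc_pair", call. = FALSE)
  (b1 == "A" & b2 == "T") | (b1 == "T" & b2 == "A") |
    (b1 == "G" & b2 == "C") | (b1 == "C" & b2 == "G")
}

.rna <- function(b) ifelse(toupper(b) == "T", "U", toupper(b))

.pair_label <- function(b_here, b_partner) {
  paste0(.rna(b_here), "-", .rna(b_partner))
}

.partner_of <- function(model, position) {
  p <- model$pairs
  i <- match(position, p$pos5)
  if (!is.na(i)) return(list(partner = p$pos3[i], wild_paired = p$wild_paired[i]))
  i <- match(position, p$pos3)
  if (!is.na(i)) return(list(partner = p$pos5[i], wild_paired = p$wild_paired[i]))
  NULL
}

#' Stem/loop location of a position
#'
#' A position is stem iff it belongs to an apposed pair of the structure
#' model; every other region position is loop.
#'
#' @param position rCRS position
#' @param model a `StructureModel`
#' @param ref optional `MtReference` for the region bounds check
#' @return "stem" or "loop"
#' @export
locate <- function(position, model, ref = NULL) {
  if (!is.null(ref) &&
      (position < ref$region_start || position > ref$region_end))
    stop("position outside region", call. = FALSE)
  if (is.null(.partner_of(model, position))) "loop" else "stem"
}

#' Watson-Crick pairing effect of a variant
#'
#' For a stem substitution, compares the WC status of the wild pair
#' (reference base, partner base) with the mutant pair (alternate base,
#' partner base): a non-WC wild pair becoming WC is `creates`; a WC wild
#' pair becoming non-WC is `abolishes`; anything else (including every loop
#' position and all indels) is `none`. Pair labels use the RNA alphabet
#' with the variant position's base first.
#'
#' @param v one-row variant data.frame (position, ref, alt, kind)
#' @param model a `StructureModel`
#' @param ref an `MtReference`
#' @return one-row data.frame: name, position, location, wc_effect,
#'   partner_position, wild_pair, mutant_pair
#' @export
wc_effect <- function(v, model, ref) {
  pos <- v$position
  loc <- locate(pos, model, ref)
  ann <- data.frame(name = if ("name" %in% names(v)) v$name else
                      name_variant(pos, v$ref, v$alt, v$kind),
                    position = pos, location = loc, wc_effect = "none",
                    partner_position = NA_integer_,
                    wild_pair = NA_character_, mutant_pair = NA_character_,
                    stringsAsFactors = FALSE)
  if (loc == "loop" || v$kind != "substitution") return(ann)
  if (ref_base(ref, pos) != v$ref)
    stop("variant ref base ", v$ref, " disagrees with reference at ", pos,
         call. = FALSE)
  pr <- .partner_of(model, pos)
  pb <- ref_base(ref, pr$partner)
  wild_wc <- is_wc_pair(v$ref, pb)
  mut_wc <- is_wc_pair(v$alt, pb)
  ann$partner_position <- pr$partner
  ann$wild_pair <- .pair_label(v$ref, pb)
  ann$mutant_pair <- .pair_label(v$alt, pb)
  ann$wc_effect <- if (!wild_wc && mut_wc) "creates"
                   else if (wild_wc && !mut_wc) "abolishes" else "none"
  ann
}

#' Annotate a variant list on the structure model
#'
#' @param variants data.frame of variants (position, ref, alt, kind, name)
#' @param model a `StructureModel`
#' @param ref an `MtReference`
#' @return list with `annotations` (one row per variant, input order) and
#'   `summary` counts (loop, stem, creates, abolishes)
#' @export
annotate_all <- function(variants, model, ref) {
  if (nrow(variants) == 0) {
    ann <- data.frame(name = character(), position = integer(),
                      location = character(), wc_effect = character(),
                      partner_position = integer(), wild_pair = character(),
                      mutant_pair = character(), stringsAsFactors = FALSE)
  } else {
    ann <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i)
      wc_effect(variants[i, , drop = FALSE], model, ref)))
    rownames(ann) <- NULL
  }
  list(annotations = ann,
       summary = c(loop = sum(ann$location == "loop"),
                   stem = sum(ann$location == "stem"),
                   creates = sum(ann$wc_effect == "creates"),
                   abolishes = sum(ann$wc_effect == "abolishes")))
}
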