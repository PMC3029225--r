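#' The conservation-index lattice
#'
#' With `n` species the CI can only take the values 100*k/n, k = 0..n,
#' rounded half-up to one decimal. For the 14-primate panel this is
#' {0, 7.1, 14.3, ..., 92.9, 100}.
#'
#' @param n_species panel size (default 14)
#' @return numeric vector of attainable one-decimal CI values
#' @export
ci_lattice <- function(n_species = 14) {
  round_half_up(100 * (0:n_species) / n_species, 1)
}

#' Species count from a one-decimal CI value
#'
#' Inverse of the lattice map; used so that threshold comparisons operate
#' on integer species counts, never on rounded percents.
#'
#' @param ci_percent one-decimal CI value(s)
#' @param n_species panel size (default 14)
#' @return integer count(s) of species matching the human base
#' @export
ci_to_matches <- function(ci_percent, n_species = 14) {
  k <- as.integer(round(ci_percent * n_species / 100))
  bad <- abs(ci_lattice(n_species)[k + 1] - round_half_up(ci_percent, 1)) > 0.05
  if (any(bad))
    stop("CI value off the ", n_species, "-species lattice: ",
         ci_percent[bad][1], call. = FALSE)
  k
}

#' Conservation index of a reference position
#'
#' The CI of a position is the percentage of panel species (human included)
#' whose aligned base equals the human wild-type base at that position.
#' Gaps and ambiguity codes in non-human rows count as non-matching.
#'
#' @param aln a `PrimateAlignment`
#' @param position rCRS position; must map to a column where the human row
#'   is not a gap
#' @return list with position, n_species_total, n_matching, ci_percent
#' @export
conservation_index <- function(aln, position) {
  col <- match(position, aln$positions)
  if (is.na(col))
    stop("unmapped position ", position,
         " (human gap or outside aligned region)", call. = FALSE)
  column <- aln$mat[, col]
  wild <- column[aln$human_row]
  n_matching <- sum(column == wild)
  list(position = as.integer(position),
       n_species_total = nrow(aln$mat),
       n_matching = as.integer(n_matching),
       ci_percent = round_half_up(100 * n_matching / nrow(aln$mat), 1))
}

#' Conservation index for a list of variants
#'
#' Substitutions are scored at their own position; insertions take the CI
#' of the named (flanking) reference position, so e.g. an insertion and a
#' substitution at the same position report the same CI.
#'
#' @param aln a `PrimateAlignment`
#' @param variants data.frame with at least `position` (and optionally
#'   `name`)
#' @return data.frame (name, position, n_matching, ci_percent), input order
#'   preserved
#' @export
ci_table <- function(aln, variants) {
  if (nrow(variants) == 0)
    return(data.frame(name = character(), position = integer(),
                      n_matching = integer(), ci_percent = numeric(),
                      stringsAsFactors = FALSE))
  res <- lapply(variants$position, function(p) conservation_index(aln, p))
  data.frame(
    name = if ("name" %in% names(variants)) variants$name else
      as.character(variants$position),
    position = vapply(res, `[[`, integer(1), "position"),
    n_matching = vapply(res, `[[`, integer(1), "n_matching"),
    ci_percent = vapply(res, `[[`, numeric(1), "ci_percent"),
    stringsAsFactors = FALSE)
}
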