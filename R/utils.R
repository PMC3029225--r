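#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.45 -> 0.5 at one decimal), the
#' convention used for all printed percentages in this package. Base R's
#' `round()` rounds half to even, which disagrees on lattice values such as
#' 100*12/14.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a count as a percentage
#'
#' Percentages are always recomputed from counts, never read from fixtures.
#' Default precision is one decimal; values below 1% are given two decimals
#' so that e.g. 2/440 renders as 0.45 rather than an ambiguous 0.5.
#'
#' @param count numerator
#' @param denominator denominator (> 0)
#' @param digits decimals for values >= 1 percent
#' @return numeric percent, rounded half-up
#' @export
percent_of <- function(count, denominator, digits = 1) {
  stopifnot(denominator > 0)
  p <- 100 * count / denominator
  ifelse(p < 1 & p > 0, round_half_up(p, 2), round_half_up(p, digits))
}

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = ".", comment.char = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv_plain <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.logical(v)) v <- ifelse(v, "yes", "no")
    v <- as.character(v)
    v[is.na(v)] <- "."
    out[[j]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

yesno_to_flag <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- v %in% c("yes", "y", "true", "1")
  bad <- !v %in% c("yes", "y", "true", "1", "no", "n", "false", "0")
  if (any(bad)) stop("unparseable yes/no value: ", v[which(bad)[1]], call. = FALSE)
  out
}

#' Path to a packaged fixture
#'
#' @param file file name under the package's extdata directory; with no
#'   argument, the directory itself
#' @return absolute path
#' @export
mito12s_extdata <- function(file = NULL) {
  if (is.null(file)) return(system.file("extdata", package = "mito12s"))
  p <- system.file("extdata", file, package = "mito12s")
  if (!nzchar(p)) stop("no packaged fixture named ", file, call. = FALSE)
  p
}
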