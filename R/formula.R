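#' Parse a Hill-notation element formula
#'
#' Parses a chemical formula string such as \code{"C6H12O6"} into a named
#' integer vector of element counts. Generic groups \code{R} and \code{X}
#' (used for polymeric or variable moieties, e.g. acyl chains or glycogenin)
#' are treated as pseudo-elements and conserved like any other element.
#'
#' @param text formula string; tokens are element symbols
#'   (\code{[A-Z][a-z]?}) or the generic groups \code{R}/\code{X}, each
#'   optionally followed by a count (implicit count is 1).
#' @return named integer vector of counts, in canonical Hill order
#'   (C first, then H, then all other symbols alphabetically; purely
#'   alphabetical when no carbon is present).
#' @examples
#' parseFormula("C6H12O6")
#' parseFormula("C47H84NO8PR")
#' @seealso [formatFormula()], [checkBalance()]
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text))
    stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (m[1] == -1L || covered != nchar(text)) {
    # locate first position not covered by a valid token
    pos <- 1L
    for (i in seq_along(toks)) {
      if (m[i] != pos) break
      pos <- pos + attr(m, "match.length")[i]
    }
    stop(sprintf("malformed formula '%s': unexpected character at position %d",
                 text, pos))
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  cnt[is.na(cnt)] <- 1L
  counts <- tapply(cnt, sym, sum)
  counts <- counts[counts > 0L]
  hillOrder(stats::setNames(as.integer(counts), names(counts)))
}

#' Format element counts as a canonical Hill string
#'
#' @param counts named integer vector as returned by [parseFormula()].
#' @return single string in Hill order; \code{""} for an empty vector.
#' @export
formatFormula <- function(counts) {
  counts <- hillOrder(counts[counts != 0])
  if (length(counts) == 0L) return("")
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

# Hill convention: C, H, then alphabetical; no C -> all alphabetical.
hillOrder <- function(counts) {
  if (length(counts) == 0L) return(counts)
  sym <- names(counts)
  if ("C" %in% sym) {
    first <- intersect(c("C", "H"), sym)
    rest <- sort(setdiff(sym, first))
    counts[c(first, rest)]
  } else {
    counts[sort(sym)]
  }
}

# Signed linear combination of formulas: sum_i coeff[i] * parse(formulas[i]).
# Returns a named numeric vector (may be negative); used by balance checking.
formulaSum <- function(formulas, coeffs) {
  acc <- numeric(0)
  for (i in seq_along(formulas)) {
    f <- parseFormula(formulas[[i]])
    for (el in names(f)) {
      acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0) + coeffs[[i]] * f[[el]]
    }
  }
  acc[acc != 0]
}

# Add/subtract formulas given as strings; helper for pathway templates where
# species formulas are built by group arithmetic so reactions balance by
# construction. parts: character vector, mult: parallel multipliers.
formulaCombine <- function(parts, mult = rep(1, length(parts))) {
  acc <- formulaSum(parts, mult)
  if (any(acc < 0))
    stop("formula combination yields negative counts: ",
         paste0(names(acc)[acc < 0], collapse = ", "))
  formatFormula(stats::setNames(as.integer(round(acc)), names(acc)))
}
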