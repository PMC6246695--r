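#' Gene-protein-reaction (GPR) boolean rules
#'
#' GPR rules state which gene products enable a reaction: \code{OR} joins
#' isoenzymes, \code{AND} joins subunits of a complex. Rules are held as
#' strings (e.g. \code{"(acox-1 and maoc-1) or daf-22"}) and canonicalized
#' to disjunctive normal form (DNF): a sorted, duplicate-free set of sorted
#' gene sets with absorbed terms removed (\code{{a}} absorbs \code{{a,b}}).
#'
#' @param text rule string; \code{and}/\code{or} (case-insensitive, also
#'   \code{&}/\code{|}) with parentheses. Gene identifiers may contain any
#'   non-blank characters except parentheses.
#' @return \code{gprParse()}: an expression tree (nested lists with
#'   \code{op}/\code{args}, leaves are gene-id strings); empty/NA input
#'   yields \code{NULL} ("no gene association").
#' @examples
#' gprCanonicalize("(a or b) and c")   # list(c("a","c"), c("b","c"))
#' gprFormat(gprOrMerge("g1", "g2"))
#' @name gpr
NULL

#' @rdname gpr
#' @export
gprParse <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text) || !nzchar(trimws(text)))
    return(NULL)
  toks <- gprTokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  tree <- gprParseOr(st)
  if (st$pos <= length(st$toks))
    stop(sprintf("malformed gene rule '%s': unexpected token '%s'",
                 text, st$toks[st$pos]))
  tree
}

gprTokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gprPeek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gprParseOr <- function(st) {
  args <- list(gprParseAnd(st))
  while (!is.na(tk <- gprPeek(st)) && tolower(tk) %in% c("or", "|", "||")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gprParseAnd(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gprParseAnd <- function(st) {
  args <- list(gprParseAtom(st))
  while (!is.na(tk <- gprPeek(st)) && tolower(tk) %in% c("and", "&", "&&")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gprParseAtom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gprParseAtom <- function(st) {
  tk <- gprPeek(st)
  if (is.na(tk)) stop("malformed gene rule: unexpected end of input")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gprParseOr(st)
    if (!identical(gprPeek(st), ")")) stop("malformed gene rule: missing ')'")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or", "&", "|", "&&", "||"))
    stop(sprintf("malformed gene rule: unexpected token '%s'", tk))
  st$pos <- st$pos + 1L
  tk
}

#' @rdname gpr
#' @param rule rule string or parsed tree.
#' @return \code{gprCanonicalize()}: canonical DNF — a list of sorted
#'   character vectors (gene sets), sorted lexicographically, absorption
#'   applied; \code{list()} for an empty rule.
#' @export
gprCanonicalize <- function(rule) {
  if (length(rule) == 1L && is.na(rule)) return(list())
  tree <- if (is.character(rule)) gprParse(rule) else rule
  if (is.null(tree)) return(list())
  dnf <- gprToDnf(tree)
  dnf <- lapply(dnf, function(s) sort(unique(s)))
  dnf <- unique(dnf)
  # absorption: drop any term that is a superset of another term
  keep <- vapply(seq_along(dnf), function(i) {
    !any(vapply(seq_along(dnf), function(j) {
      j != i && length(dnf[[j]]) < length(dnf[[i]]) && all(dnf[[j]] %in% dnf[[i]])
    }, logical(1)))
  }, logical(1))
  dnf <- dnf[keep]
  dnf[order(vapply(dnf, paste, collapse = "\r", FUN.VALUE = ""))]
}

gprToDnf <- function(tree) {
  if (is.character(tree)) return(list(tree))
  parts <- lapply(tree$args, gprToDnf)
  if (tree$op == "or") return(do.call(c, parts))
  # and: cartesian product of disjunct sets
  acc <- parts[[1]]
  for (p in parts[-1]) {
    acc <- unlist(lapply(acc, function(a) lapply(p, function(b) c(a, b))),
                  recursive = FALSE)
  }
  acc
}

#' @rdname gpr
#' @param dnf canonical DNF as returned by [gprCanonicalize()].
#' @return \code{gprFormat()}: rule string (\code{NA} for an empty rule).
#' @export
gprFormat <- function(dnf) {
  if (is.character(dnf)) dnf <- gprCanonicalize(dnf)
  if (length(dnf) == 0L) return(NA_character_)
  terms <- vapply(dnf, function(s) {
    t <- paste(s, collapse = " and ")
    if (length(s) > 1L && length(dnf) > 1L) paste0("(", t, ")") else t
  }, "")
  paste(terms, collapse = " or ")
}

#' @rdname gpr
#' @param rule1,rule2 rule strings (either may be \code{NA}/empty).
#' @return \code{gprOrMerge()}: the canonical rule string of
#'   \code{rule1 OR rule2}; isoenzyme semantics for reactions merged from
#'   two source models.
#' @export
gprOrMerge <- function(rule1, rule2) {
  d1 <- gprCanonicalize(rule1)
  d2 <- gprCanonicalize(rule2)
  gprFormat(gprCanonicalize(list(op = "or", args = c(
    lapply(d1, function(s) if (length(s) == 1L) s[[1]] else list(op = "and", args = as.list(s))),
    lapply(d2, function(s) if (length(s) == 1L) s[[1]] else list(op = "and", args = as.list(s)))
  ))))
}

#' @rdname gpr
#' @return \code{gprGenes()}: character vector of all gene ids in a rule.
#' @export
gprGenes <- function(rule) {
  sort(unique(unlist(gprCanonicalize(rule))))
}

#' @rdname gpr
#' @param map named character vector old-id -> new-id.
#' @return \code{gprRename()}: rule string with leaves renamed, re-canonicalized.
#' @export
gprRename <- function(rule, map) {
  dnf <- gprCanonicalize(rule)
  if (length(dnf) == 0L) return(NA_character_)
  dnf <- lapply(dnf, function(s) {
    hit <- s %in% names(map)
    s[hit] <- unname(map[s[hit]])
    s
  })
  gprFormat(gprCanonicalize(list(op = "or", args = lapply(dnf, function(s)
    if (length(s) == 1L) s[[1]] else list(op = "and", args = as.list(s))))))
}

#' @rdname gpr
#' @return \code{gprEqual()}: TRUE when two rules have identical canonical DNF.
#' @export
gprEqual <- function(rule1, rule2) {
  identical(gprCanonicalize(rule1), gprCanonicalize(rule2))
}
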