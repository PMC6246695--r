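# Independent oracles used to cross-check package operations. These stay
# deliberately separate from the implementation paths they verify.

# Truth-table evaluation of a GPR rule string via R's own parser: each gene
# is substituted by TRUE/FALSE and the boolean expression evaluated. Only
# used with syntactically R-safe gene names (letters/digits).
evalRuleOracle <- function(rule, assignment) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule)))
    return(FALSE)
  expr <- rule
  expr <- gsub("\\bor\\b", "||", expr, ignore.case = TRUE)
  expr <- gsub("\\band\\b", "&&", expr, ignore.case = TRUE)
  for (g in names(assignment))
    expr <- gsub(paste0("\\b", g, "\\b"),
                 if (assignment[[g]]) "TRUE" else "FALSE", expr)
  eval(parse(text = expr))
}

# exhaustive equivalence of two rules over their joint gene set (<= 10 genes)
rulesEquivalentOracle <- function(rule1, rule2) {
  gs <- sort(unique(c(gprGenes(rule1), gprGenes(rule2))))
  stopifnot(length(gs) <= 10)
  if (length(gs) == 0) return(TRUE)
  for (mask in 0:(2^length(gs) - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_along(gs) - 1)))
    a <- stats::setNames(as.list(bits), gs)
    if (evalRuleOracle(rule1, a) != evalRuleOracle(rule2, a)) return(FALSE)
  }
  TRUE
}

# rule string from a canonical DNF, for feeding the oracle
dnfToRuleString <- function(dnf) {
  if (length(dnf) == 0) return(NA_character_)
  paste(vapply(dnf, function(s) paste0("(", paste(s, collapse = " and "), ")"),
               ""), collapse = " or ")
}

# Independent LP ranges via scipy's HiGHS solver (a completely separate
# implementation from the simplex behind fba/fva). One python call ranges
# every requested objective: min and max of c.v s.t. S v = 0,
# lb <= v <= ub.
scipyRangesOracle <- function(S, lb, ub, objectives = seq_along(lb)) {
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(list(S = S, lb = lb, ub = ub,
                            obj = as.integer(objectives - 1L)),
                       fin, digits = NA, auto_unbox = FALSE, matrix = "rowmajor")
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog
d = json.load(open(sys.argv[1]))
S = np.array(d["S"], dtype=float); lb = d["lb"]; ub = d["ub"]
bounds = list(zip(lb, ub)); n = S.shape[1]
out = {"min": [], "max": []}
for j in d["obj"]:
    c = np.zeros(n); c[j] = 1.0
    lo = linprog(c, A_eq=S, b_eq=np.zeros(S.shape[0]), bounds=bounds, method="highs")
    hi = linprog(-c, A_eq=S, b_eq=np.zeros(S.shape[0]), bounds=bounds, method="highs")
    out["min"].append(lo.fun if lo.status == 0 else None)
    out["max"].append(-hi.fun if hi.status == 0 else None)
json.dump(out, open(sys.argv[2], "w"))
'
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  status <- system2("python", c(sf, fin, fout), stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  res <- jsonlite::read_json(fout, simplifyVector = FALSE)
  toNum <- function(v) vapply(v, function(x) if (is.null(x)) NA_real_ else
    as.numeric(x), 0)
  list(min = toNum(res$min), max = toNum(res$max))
}

modelMatrices <- function(model, freeGrowth = TRUE) {
  rxn <- reactions(model)
  metIds <- metabolites(model)$id
  S <- matrix(0, length(metIds), nrow(rxn), dimnames = list(metIds, rxn$id))
  for (i in seq_len(nrow(rxn))) S[names(rxn$stoich[[i]]), i] <- rxn$stoich[[i]]
  lb <- rxn$lb; ub <- rxn$ub
  if (freeGrowth) { lb[rxn$is_exchange] <- -1000; ub[rxn$is_exchange] <- 1000 }
  list(S = S, lb = lb, ub = ub, ids = rxn$id)
}

lpOracle <- function(S, lb, ub, cc, maximize = TRUE) {
  j <- which(cc != 0)
  stopifnot(length(j) == 1L, cc[j] == 1)
  r <- scipyRangesOracle(S, lb, ub, objectives = j)
  if (maximize) r$max[1] else r$min[1]
}

# brute-force blocked set: per reaction, two independent LPs (scipy)
blockedOracle <- function(model, tolerance = 1e-6) {
  p <- modelMatrices(model, freeGrowth = TRUE)
  r <- scipyRangesOracle(p$S, p$lb, p$ub)
  ok <- !is.na(r$min) & !is.na(r$max) &
    abs(r$min) < tolerance & abs(r$max) < tolerance
  sort(p$ids[ok])
}

# all-pairs duplicate scan by direct signature comparison (no removal
# bookkeeping): which second-model reactions have a signature-equal twin
bruteForceDuplicates <- function(model, primary, config = mergeConfig()) {
  rxn <- reactions(model)
  first <- which(rxn$source == primary)
  second <- which(rxn$source != primary)
  sigF <- vapply(seq_len(nrow(rxn)), function(i)
    canonicalSignature(rxn[i, , drop = FALSE], model, config)$string, "")
  sigP <- vapply(seq_len(nrow(rxn)), function(i)
    canonicalSignature(rxn[i, , drop = FALSE], model, config,
                       strip_protons = TRUE)$string, "")
  hits <- character(0)
  for (j in second) {
    if (config$keep_biomass && rxn$is_biomass[j]) next
    twin <- any(vapply(first, function(i)
      !(config$keep_biomass && rxn$is_biomass[i]) &&
        (sigF[i] == sigF[j] || sigP[i] == sigP[j]), logical(1)))
    if (twin) hits <- c(hits, rxn$id[j])
  }
  sort(hits)
}

# small hand-checkable chain model: EX_up (ub uptake) -> A -> B -> EX_out
chainModel <- function(uptake = 10) {
  m <- newModel("chain", c(c = "cytosol", e = "extracellular"))
  m <- addMetabolite(m, "A_c")
  m <- addMetabolite(m, "B_c")
  m <- addReaction(m, "EX_up", c(A_c = 1), lb = 0, ub = uptake)
  m <- addReaction(m, "R_AB", c(A_c = -1, B_c = 1), lb = 0, ub = 1000)
  m <- addReaction(m, "EX_out", c(B_c = -1), lb = 0, ub = 1000)
  m
}

# textbook balanced fixture: 2 H2 + O2 -> 2 H2O
waterModel <- function() {
  m <- newModel("water", c(c = "cytosol"))
  m <- addMetabolite(m, "h2_c", formula = "H2", charge = 0)
  m <- addMetabolite(m, "o2_c", formula = "O2", charge = 0)
  m <- addMetabolite(m, "h2o_c", formula = "H2O", charge = 0)
  addReaction(m, "WATER", c(h2_c = -2, o2_c = -1, h2o_c = 2), lb = 0)
}
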