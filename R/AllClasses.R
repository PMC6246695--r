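#' @import methods
NULL

#' GSModel: a genome-scale constraint-based metabolic model
#'
#' The central container moved through every stage of reconciliation,
#' merging and flux analysis. Metabolites and reactions are held as
#' data.frames with list-columns (annotations, stoichiometries), the
#' compact representation used by constraint-based modelling toolboxes.
#'
#' @slot id model identifier.
#' @slot compartments named character vector, id -> display name.
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{formula} (Hill string or NA), \code{charge}
#'   (integer or NA), and list-columns \code{annotations} (named list of
#'   character vectors, database -> accessions) and \code{notes}.
#' @slot reactions data.frame with columns \code{id}, \code{lb}, \code{ub},
#'   \code{reversible}, \code{gene_rule} (rule string or NA),
#'   \code{subsystem}, \code{is_biomass}, \code{is_exchange}, \code{source}
#'   (provenance tag carried through merges), and list-columns
#'   \code{stoich} (named numeric, negative = substrate) and \code{notes}.
#' @slot genes character vector of gene ids.
#' @slot objective id of the objective (biomass) reaction, or NA.
#'
#' @seealso [newModel()], [addMetabolite()], [addReaction()],
#'   [validateModel()], [fba()]
#' @export
setClass("GSModel", representation(
  id = "character",
  compartments = "character",
  metabolites = "data.frame",
  reactions = "data.frame",
  genes = "character",
  objective = "character"
))

setValidity("GSModel", function(object) {
  msgs <- character(0)
  met <- object@metabolites
  rxn <- object@reactions
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicate reaction ids")
  if (nrow(met) && !all(met$compartment %in% names(object@compartments)))
    msgs <- c(msgs, "metabolite in undeclared compartment")
  if (nrow(rxn)) {
    keys <- unique(unlist(lapply(rxn$stoich, names)))
    if (!all(keys %in% met$id))
      msgs <- c(msgs, paste0("unresolved species reference(s): ",
                             paste(setdiff(keys, met$id), collapse = ", ")))
    if (any(rxn$lb > rxn$ub)) msgs <- c(msgs, "lower bound exceeds upper bound")
  }
  if (length(object@objective) != 1L)
    msgs <- c(msgs, "objective must be length 1 (possibly NA)")
  if (length(msgs)) msgs else TRUE
})

#' MergeReport: bookkeeping of a model merge
#'
#' Counts follow the union convention of consensus-model building:
#' \code{nMetabolitesUnion}, \code{nGenesUnion}, \code{nReactionsUnion} are
#' the sizes after concatenation (before duplicate-reaction removal);
#' \code{removedPairs} records every duplicate elimination with its match
#' mode (\code{exact} or \code{proton}), whether gene rules were OR-merged,
#' and which side won elemental-balance arbitration.
#'
#' @export
setClass("MergeReport", representation(
  nMetabolitesUnion = "integer",
  nGenesUnion = "integer",
  nReactionsUnion = "integer",
  nDuplicatesRemoved = "integer",
  nGprMerged = "integer",
  nBalanceCorrected = "integer",
  removedPairs = "data.frame",
  revertedMerges = "data.frame",
  curationFlags = "data.frame"
))

#' BalanceReport: elemental and charge balance of one reaction
#'
#' Imbalances are products minus substrates; \code{balanced} is TRUE only
#' when every element (generic groups R/X included) and the charge balance
#' to zero and all participants had formula and charge ("undetermined" is
#' never treated as balanced).
#'
#' @export
setClass("BalanceReport", representation(
  reaction = "character",
  elementImbalance = "numeric",
  chargeImbalance = "numeric",
  balanced = "logical",
  determined = "logical",
  reason = "character"
))

#' CoverageReport: entity partition between model and detected metabolites
#'
#' Entities are InChIKey connectivity blocks (first 14 characters), so
#' stereoisomers and protonation states collapse to one entity per source.
#'
#' @export
setClass("CoverageReport", representation(
  nModelEntities = "integer",
  nDetectedEntities = "integer",
  overlap = "character",
  modelOnly = "character",
  detectedOnly = "character",
  nModelNoKey = "integer",
  nDetectedNoKey = "integer"
))

setMethod("show", "GSModel", function(object) {
  cat("GSModel:", object@id, "\n")
  cat("  compartments:", length(object@compartments),
      paste0("(", paste(names(object@compartments), collapse = ", "), ")"), "\n")
  cat("  metabolites: ", nrow(object@metabolites), "\n")
  cat("  reactions:   ", nrow(object@reactions), "\n")
  cat("  genes:       ", length(object@genes), "\n")
  cat("  objective:   ", object@objective, "\n")
})

setMethod("show", "MergeReport", function(object) {
  cat("MergeReport\n")
  cat(sprintf("  union sizes: %d metabolites, %d genes, %d reactions\n",
              object@nMetabolitesUnion, object@nGenesUnion, object@nReactionsUnion))
  cat(sprintf("  duplicates removed: %d (GPR OR-merged: %d, balance-corrected: %d)\n",
              object@nDuplicatesRemoved, object@nGprMerged, object@nBalanceCorrected))
  if (nrow(object@revertedMerges))
    cat(sprintf("  reverted merges: %d\n", nrow(object@revertedMerges)))
  if (nrow(object@curationFlags))
    cat(sprintf("  flagged for manual curation: %d\n", nrow(object@curationFlags)))
})

setMethod("show", "BalanceReport", function(object) {
  cat("BalanceReport for", object@reaction, "\n")
  if (!object@determined) {
    cat("  undetermined:", object@reason, "\n")
  } else if (object@balanced) {
    cat("  balanced\n")
  } else {
    if (length(object@elementImbalance))
      cat("  element imbalance:",
          paste(sprintf("%s:%+g", names(object@elementImbalance),
                        object@elementImbalance), collapse = " "), "\n")
    if (object@chargeImbalance != 0)
      cat("  charge imbalance:", sprintf("%+g", object@chargeImbalance), "\n")
  }
})

setMethod("show", "CoverageReport", function(object) {
  cat("CoverageReport\n")
  cat(sprintf("  model entities:    %d\n", object@nModelEntities))
  cat(sprintf("  detected entities: %d\n", object@nDetectedEntities))
  cat(sprintf("  overlap: %d  model-only: %d  detected-only: %d\n",
              length(object@overlap), length(object@modelOnly),
              length(object@detectedOnly)))
})
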