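#' Merge configuration
#'
#' @param proton_ids metabolite ids treated as protons during
#'   proton-stripped rematching; default one per conventional compartment.
#'   Water is deliberately not stripped.
#' @param balance_arbitration when TRUE (default), a proton-stripped match
#'   is arbitrated by elemental balance: the balanced version's
#'   stoichiometry wins.
#' @param keep_biomass biomass reactions are never removed as duplicates
#'   (both source models' biomass reactions are kept for later evaluation).
#' @param tolerance viability threshold (flux units) for [guardedMerge()].
#' @return a list of class \code{"mergeConfig"}.
#' @export
mergeConfig <- function(proton_ids = c("h_c", "h_m", "h_n", "h_e"),
                        balance_arbitration = TRUE,
                        keep_biomass = TRUE,
                        tolerance = 1e-6) {
  stopifnot(length(proton_ids) >= 1L)
  structure(list(proton_ids = proton_ids,
                 balance_arbitration = balance_arbitration,
                 keep_biomass = keep_biomass,
                 tolerance = tolerance),
            class = "mergeConfig")
}

#' Concatenate two models
#'
#' Union of compartments, metabolites (same-id entries collapsed, meta
#' information combined), genes and reactions. All reactions are retained;
#' a reaction-id clash with different stoichiometry keeps both, suffixing
#' the second. Every reaction is tagged with its model of origin in the
#' \code{source} column, which the duplicate scan requires.
#'
#' @param m1,m2 [GSModel-class] objects in a common namespace (run the
#'   reconciliation step first).
#' @return list(model, report); the [MergeReport-class] carries the union
#'   counts (metabolites, genes, reactions including duplicates).
#' @export
concatModels <- function(m1, m2) {
  comps <- c(m1@compartments,
             m2@compartments[setdiff(names(m2@compartments),
                                     names(m1@compartments))])
  out <- newModel(paste0(m1@id, "+", m2@id), comps)
  met1 <- m1@metabolites; met2 <- m2@metabolites
  met <- met1
  for (i in seq_len(nrow(met2))) {
    j <- match(met2$id[i], met$id)
    if (is.na(j)) {
      met <- rbind(met, met2[i, , drop = FALSE])
    } else {
      met$annotations[[j]] <- unionAnnotations(met$annotations[[j]],
                                               met2$annotations[[i]])
      if (is.na(met$charge[j])) met$charge[j] <- met2$charge[i]
      if (is.na(met$formula[j])) met$formula[j] <- met2$formula[i]
    }
  }
  rxn1 <- m1@reactions; rxn2 <- m2@reactions
  if (nrow(rxn1)) rxn1$source <- ifelse(is.na(rxn1$source), m1@id, rxn1$source)
  if (nrow(rxn2)) rxn2$source <- ifelse(is.na(rxn2$source), m2@id, rxn2$source)
  clashes <- intersect(rxn1$id, rxn2$id)
  for (cl in clashes) {
    i <- match(cl, rxn2$id)
    rxn2$id[i] <- paste0(cl, "_", m2@id)
    warning("reaction id clash on '", cl, "': second model's copy kept as '",
            rxn2$id[i], "'")
  }
  out@metabolites <- met
  out@reactions <- rbind(rxn1, rxn2)
  out@genes <- sort(union(m1@genes, m2@genes))
  out@objective <- if (!is.na(m1@objective)) m1@objective else m2@objective
  report <- new("MergeReport",
                nMetabolitesUnion = nrow(met),
                nGenesUnion = length(out@genes),
                nReactionsUnion = nrow(out@reactions),
                nDuplicatesRemoved = 0L, nGprMerged = 0L,
                nBalanceCorrected = 0L,
                removedPairs = emptyRemovedPairs(),
                revertedMerges = emptyReverted(),
                curationFlags = emptyCuration())
  list(model = out, report = report)
}

emptyRemovedPairs <- function()
  data.frame(kept_id = character(0), removed_id = character(0),
             match_mode = character(0), gpr_merged = logical(0),
             balance_winner = character(0), stringsAsFactors = FALSE)
emptyReverted <- function()
  data.frame(keep_id = character(0), drop_id = character(0),
             reason = character(0), stringsAsFactors = FALSE)
emptyCuration <- function()
  data.frame(id1 = character(0), id2 = character(0), reason = character(0),
             stringsAsFactors = FALSE)

#' Canonical stoichiometric signature of a reaction
#'
#' Participants are keyed by compartment-stripped metabolite id, sorted by
#' (key, compartment); for reversible reactions the orientation is
#' normalized so the lexicographically smallest participant carries a
#' negative sign, making a reaction and its reverse indistinguishable.
#' Irreversible reactions keep their direction. Coefficients are compared
#' exactly — no rescaling, so \code{2A -> 2B} and \code{A -> B} differ.
#'
#' @param reaction reaction id or single-row slice of reactions(model).
#' @param model a [GSModel-class].
#' @param config a [mergeConfig()].
#' @param strip_protons drop proton entries before normalizing
#'   (see [stripProtons()]).
#' @return object of class \code{"reactionSignature"}: list with
#'   \code{entries} (data.frame key/compartment/coeff), \code{string}
#'   (the comparable canonical form), \code{proton_stripped}.
#' @export
canonicalSignature <- function(reaction, model, config = mergeConfig(),
                               strip_protons = FALSE) {
  if (is.character(reaction)) {
    i <- reactionRow(model, reaction)
    if (is.na(i)) stop("no such reaction: ", reaction)
    reaction <- model@reactions[i, , drop = FALSE]
  }
  s <- reaction$stoich[[1]]
  if (strip_protons) s <- s[!(names(s) %in% config$proton_ids)]
  known <- names(model@compartments)
  keys <- vapply(names(s), metaboliteKey, "", known = known)
  comps <- vapply(names(s), function(id) {
    cp <- metaboliteCompartment(id, known)
    if (is.na(cp)) "" else cp
  }, "")
  ord <- order(keys, comps)
  keys <- keys[ord]; comps <- comps[ord]; co <- unname(s[ord])
  if (isTRUE(reaction$reversible) && length(co) && co[1] > 0) co <- -co
  entries <- data.frame(key = keys, compartment = comps, coeff = co,
                        stringsAsFactors = FALSE)
  string <- paste0(if (strip_protons) "p|" else "f|",
                   if (isTRUE(reaction$reversible)) "rev|" else "irr|",
                   paste(keys, comps,
                         vapply(co, formatCoefficient, ""),
                         sep = "@", collapse = "|"))
  structure(list(entries = entries, string = string,
                 proton_stripped = strip_protons,
                 reversible = isTRUE(reaction$reversible)),
            class = "reactionSignature")
}

#' Strip protons from a signature
#'
#' Removes all proton entries (per-compartment ids from the config) and
#' flags the signature, so that two reactions differing only in their
#' proton bookkeeping compare equal. Orientation is re-normalized on the
#' remaining participants.
#'
#' @param signature a \code{"reactionSignature"}.
#' @param config a [mergeConfig()].
#' @return a proton-stripped \code{"reactionSignature"}.
#' @export
stripProtons <- function(signature, config = mergeConfig()) {
  e <- signature$entries
  protonKeys <- unique(vapply(config$proton_ids, function(p)
    sub("_[^_]*$", "", p), ""))
  drop <- e$key %in% protonKeys &
    paste0(e$key, "_", e$compartment) %in% config$proton_ids
  e <- e[!drop, , drop = FALSE]
  co <- e$coeff
  if (signature$reversible && length(co) && co[1] > 0) co <- -co
  e$coeff <- co
  structure(list(entries = e,
                 string = paste0("p|",
                   if (signature$reversible) "rev|" else "irr|",
                   paste(e$key, e$compartment,
                         vapply(e$coeff, formatCoefficient, ""),
                         sep = "@", collapse = "|")),
                 proton_stripped = TRUE,
                 reversible = signature$reversible),
            class = "reactionSignature")
}

#' Remove duplicate reactions after a model concatenation
#'
#' Implements the first-model-primacy duplicate scan: for each reaction of
#' the primary source, second-source reactions are compared by canonical
#' signature. An exact match removes the second copy (OR-merging the gene
#' rules when they differ); failing that, proton-stripped signatures are
#' compared, and on a match elemental balance arbitrates which
#' stoichiometry survives — when the second model's version is the
#' balanced one, its stoichiometry and meta information replace the
#' first's. Biomass reactions are never removed. Pairs where both versions
#' are unbalanced are kept and flagged for manual curation.
#'
#' @param model model produced by [concatModels()] (reactions carry
#'   \code{source} tags).
#' @param primary_source source tag of the first model; defaults to the
#'   tag of the first reaction.
#' @param config a [mergeConfig()].
#' @return list(model, report): [MergeReport-class] with one
#'   \code{removedPairs} row per removal (\code{match_mode} exact/proton,
#'   \code{gpr_merged}, \code{balance_winner} first/second/both/none).
#' @export
deduplicateReactions <- function(model, primary_source = NULL,
                                 config = mergeConfig()) {
  rxn <- model@reactions
  if (nrow(rxn) == 0L)
    return(list(model = model, report = new("MergeReport",
      nMetabolitesUnion = nrow(model@metabolites),
      nGenesUnion = length(model@genes), nReactionsUnion = 0L,
      nDuplicatesRemoved = 0L, nGprMerged = 0L, nBalanceCorrected = 0L,
      removedPairs = emptyRemovedPairs(), revertedMerges = emptyReverted(),
      curationFlags = emptyCuration())))
  if (is.null(primary_source)) primary_source <- rxn$source[1]
  first <- which(rxn$source == primary_source)
  second <- which(rxn$source != primary_source)
  sigF <- vapply(seq_len(nrow(rxn)), function(i)
    canonicalSignature(rxn[i, , drop = FALSE], model, config)$string, "")
  sigP <- vapply(seq_len(nrow(rxn)), function(i)
    canonicalSignature(rxn[i, , drop = FALSE], model, config,
                       strip_protons = TRUE)$string, "")
  removed <- rep(FALSE, nrow(rxn))
  pairs <- list(); flags <- list()
  nGpr <- 0L; nBal <- 0L
  for (i in first) {
    if (config$keep_biomass && rxn$is_biomass[i]) next
    for (j in second) {
      if (removed[j]) next
      if (config$keep_biomass && rxn$is_biomass[j]) next
      mode <- NULL; winner <- NA_character_
      if (sigF[j] == sigF[i]) {
        mode <- "exact"
      } else if (sigP[j] == sigP[i]) {
        # proton-variant: arbitrate by elemental balance
        b1 <- checkBalance(rxn[i, , drop = FALSE], model)
        b2 <- checkBalance(rxn[j, , drop = FALSE], model)
        ok1 <- b1@determined && b1@balanced
        ok2 <- b2@determined && b2@balanced
        if (!ok1 && !ok2) {
          flags[[length(flags) + 1L]] <- data.frame(
            id1 = rxn$id[i], id2 = rxn$id[j],
            reason = "proton-variant pair, both unbalanced",
            stringsAsFactors = FALSE)
          next
        }
        mode <- "proton"
        winner <- if (ok1 && ok2) "both" else if (ok1) "first" else "second"
        if (config$balance_arbitration && winner == "second") {
          # second model's version is the correct one: adopt its
          # stoichiometry and meta information
          rxn$stoich[[i]] <- rxn$stoich[[j]]
          rxn$notes[[i]] <- rxn$notes[[j]]
          rxn$subsystem[i] <- rxn$subsystem[j]
          rxn$lb[i] <- rxn$lb[j]; rxn$ub[i] <- rxn$ub[j]
          rxn$reversible[i] <- rxn$reversible[j]
          sigF[i] <- sigF[j]; sigP[i] <- sigP[j]
          nBal <- nBal + 1L
        }
      }
      if (is.null(mode)) next
      gprM <- FALSE
      if (!gprEqual(rxn$gene_rule[i], rxn$gene_rule[j])) {
        rxn$gene_rule[i] <- gprOrMerge(rxn$gene_rule[i], rxn$gene_rule[j])
        gprM <- TRUE
        nGpr <- nGpr + 1L
      }
      removed[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        kept_id = rxn$id[i], removed_id = rxn$id[j], match_mode = mode,
        gpr_merged = gprM, balance_winner = winner, stringsAsFactors = FALSE)
    }
  }
  model@reactions <- rxn[!removed, , drop = FALSE]
  rownames(model@reactions) <- NULL
  removedPairs <- if (length(pairs)) do.call(rbind, pairs) else emptyRemovedPairs()
  report <- new("MergeReport",
                nMetabolitesUnion = nrow(model@metabolites),
                nGenesUnion = length(model@genes),
                nReactionsUnion = length(removed),
                nDuplicatesRemoved = sum(removed),
                nGprMerged = nGpr, nBalanceCorrected = nBal,
                removedPairs = removedPairs,
                revertedMerges = emptyReverted(),
                curationFlags = if (length(flags)) do.call(rbind, flags)
                  else emptyCuration())
  list(model = model, report = report)
}

#' Viability-guarded iterative merging
#'
#' Applies duplicate-removal candidates one at a time; after each, the
#' model must still carry flux through its objective (biomass) reaction in
#' a free-growth simulation. If the merge is inviable, the change is
#' reverted and recorded.
#'
#' @param model a [GSModel-class].
#' @param candidate_pairs data.frame with columns \code{keep_id},
#'   \code{drop_id}: suggested duplicate removals.
#' @param objective objective reaction id; defaults to the model's.
#' @param config a [mergeConfig()]; \code{tolerance} is the minimum
#'   objective flux counted as viable.
#' @return list(model, report): the report's \code{revertedMerges} lists
#'   every reverted candidate.
#' @export
guardedMerge <- function(model, candidate_pairs, objective = NULL,
                         config = mergeConfig()) {
  if (is.null(objective)) objective <- model@objective
  if (is.na(objective) || !(objective %in% model@reactions$id))
    stop("objective reaction not found: ", objective)
  base <- fba(model, objective, mode = "free-growth")
  if (base$status != "optimal" || base$objective <= config$tolerance)
    stop("starting model is not viable (status ", base$status,
         ", objective ", signif(base$objective %||% NA, 4),
         "); aborting guarded merge")
  reverted <- list(); applied <- list()
  if (is.null(candidate_pairs) || nrow(candidate_pairs) == 0L)
    candidate_pairs <- data.frame(keep_id = character(0),
                                  drop_id = character(0))
  for (k in seq_len(nrow(candidate_pairs))) {
    keep <- candidate_pairs$keep_id[k]; drop <- candidate_pairs$drop_id[k]
    i <- reactionRow(model, keep); j <- reactionRow(model, drop)
    if (is.na(j)) next
    trial <- model
    if (!is.na(i) && !gprEqual(trial@reactions$gene_rule[i],
                               trial@reactions$gene_rule[j]))
      trial@reactions$gene_rule[i] <-
        gprOrMerge(trial@reactions$gene_rule[i], trial@reactions$gene_rule[j])
    trial@reactions <- trial@reactions[-j, , drop = FALSE]
    sol <- fba(trial, objective, mode = "free-growth")
    if (sol$status == "optimal" && sol$objective > config$tolerance) {
      model <- trial
      applied[[length(applied) + 1L]] <-
        data.frame(keep_id = keep, drop_id = drop, stringsAsFactors = FALSE)
    } else {
      reverted[[length(reverted) + 1L]] <- data.frame(
        keep_id = keep, drop_id = drop,
        reason = if (sol$status != "optimal") sol$status else "objective below tolerance",
        stringsAsFactors = FALSE)
    }
  }
  report <- new("MergeReport",
                nMetabolitesUnion = nrow(model@metabolites),
                nGenesUnion = length(model@genes),
                nReactionsUnion = nrow(model@reactions) + length(applied),
                nDuplicatesRemoved = length(applied),
                nGprMerged = 0L, nBalanceCorrected = 0L,
                removedPairs = if (length(applied)) {
                  ap <- do.call(rbind, applied)
                  data.frame(kept_id = ap$keep_id, removed_id = ap$drop_id,
                             match_mode = "guarded", gpr_merged = NA,
                             balance_winner = NA_character_,
                             stringsAsFactors = FALSE)
                } else emptyRemovedPairs(),
                revertedMerges = if (length(reverted)) do.call(rbind, reverted)
                  else emptyReverted(),
                curationFlags = emptyCuration())
  list(model = model, report = report)
}
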