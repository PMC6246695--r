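#' Read an identifier mapping table
#'
#' Mapping tables are frozen local TSV files (database downloads drift, so
#' reconciliation works only against shipped snapshots). Columns:
#' \code{namespace}, \code{source_id}, \code{target_id}, optional
#' \code{xrefs} (\code{db:acc;db:acc} syntax), \code{charge},
#' \code{formula}.
#'
#' @param path TSV file with header.
#' @return data.frame with parsed \code{xrefs} list-column.
#' @export
readMappingTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "")
  need <- c("namespace", "source_id", "target_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mapping table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df[, c("namespace", "source_id")]))
    stop("mapping table has duplicate (namespace, source_id) rows")
  if (any(is.na(df$target_id) | !nzchar(df$target_id)))
    stop("mapping table has empty target_id")
  df$xrefs <- I(lapply(
    if ("xrefs" %in% names(df)) df$xrefs else rep(NA_character_, nrow(df)),
    function(x) if (is.na(x)) list() else parseAnnotationField(x)))
  df$charge <- if ("charge" %in% names(df))
    suppressWarnings(as.numeric(df$charge)) else NA_real_
  if (!"formula" %in% names(df)) df$formula <- NA_character_
  df
}

#' Map gene identifiers to a canonical namespace
#'
#' Rewrites every mappable gene in the model's gene set and in all GPR
#' rules; aliases that collapse to one target reduce the unique-gene
#' count. Unmapped genes are kept verbatim and reported.
#'
#' @param model a [GSModel-class].
#' @param table mapping table from [readMappingTable()] (one target
#'   namespace, e.g. WormBase \code{WBGene} ids).
#' @return list with elements \code{model} and \code{report}
#'   (\code{mapped}, \code{unmapped}, \code{nCollapsed}).
#' @export
mapGeneIds <- function(model, table) {
  map <- stats::setNames(table$target_id, table$source_id)
  old <- model@genes
  hit <- old %in% names(map)
  newIds <- ifelse(hit, unname(map[old]), old)
  before <- length(unique(old))
  model@genes <- sort(unique(newIds))
  rename <- stats::setNames(newIds[hit], old[hit])
  rxn <- model@reactions
  for (i in seq_len(nrow(rxn))) {
    if (!is.na(rxn$gene_rule[i]) && length(rename))
      rxn$gene_rule[i] <- gprRename(rxn$gene_rule[i], rename)
  }
  model@reactions <- rxn
  list(model = model,
       report = list(mapped = stats::setNames(newIds[hit], old[hit]),
                     unmapped = old[!hit],
                     nCollapsed = before - length(model@genes)))
}

#' Normalize metabolite identifiers to a common namespace
#'
#' Renames mapped metabolites (the trailing compartment suffix is
#' preserved), folds the table's cross-references, charge and formula into
#' the metabolite annotations, and flags collisions — two distinct
#' in-compartment metabolites mapping to one target — as duplicate
#' candidates without auto-merging them.
#'
#' @inheritParams mapGeneIds
#' @return list(model, report); report lists \code{unmapped} ids and a
#'   \code{collisions} data.frame.
#' @seealso [deduplicateMetabolites()] for resolving flagged collisions.
#' @export
normalizeMetaboliteIds <- function(model, table) {
  map <- stats::setNames(table$target_id, table$source_id)
  met <- model@metabolites
  known <- names(model@compartments)
  keys <- vapply(met$id, metaboliteKey, "", known = known)
  comps <- met$compartment
  hit <- keys %in% names(map)
  proposed <- ifelse(hit, paste0(unname(map[keys]), "_", comps), met$id)
  # collisions: proposed id already taken by a different source metabolite
  tab <- table(proposed)
  collided <- proposed %in% names(tab)[tab > 1] & proposed != met$id
  collisions <- data.frame(source_id = met$id[collided],
                           target_id = proposed[collided],
                           stringsAsFactors = FALSE)
  doRename <- hit & !collided & !(proposed %in% met$id[!hit])
  rename <- stats::setNames(proposed[doRename], met$id[doRename])
  for (i in which(hit)) {
    row <- match(keys[i], table$source_id)
    ann <- met$annotations[[i]]
    ann <- unionAnnotations(ann, table$xrefs[[row]])
    met$annotations[[i]] <- ann
    if (is.na(met$charge[i]) && !is.na(table$charge[row]))
      met$charge[i] <- table$charge[row]
    if (is.na(met$formula[i]) && !is.na(table$formula[row]))
      met$formula[i] <- table$formula[row]
  }
  met$id[met$id %in% names(rename)] <-
    unname(rename[met$id[met$id %in% names(rename)]])
  model@metabolites <- met
  if (length(rename)) {
    rxn <- model@reactions
    for (i in seq_len(nrow(rxn))) {
      s <- rxn$stoich[[i]]
      nm <- names(s)
      tohit <- nm %in% names(rename)
      nm[tohit] <- unname(rename[nm[tohit]])
      names(s) <- nm
      rxn$stoich[[i]] <- s
    }
    model@reactions <- rxn
  }
  list(model = model,
       report = list(renamed = rename,
                     unmapped = met$id[!hit],
                     collisions = collisions))
}

#' Merge duplicate metabolites sharing an annotation key
#'
#' Within each compartment, metabolites sharing the key value are merged
#' into one survivor (the lexicographically smallest id — a deterministic
#' tie-break); reaction stoichiometries are rewired to the survivor and
#' annotations unioned. If both duplicates occurred in one reaction the
#' coefficients are summed; a zero net coefficient removes the metabolite
#' from that reaction and is logged.
#'
#' @param model a [GSModel-class].
#' @param key annotation database used as identity key, or \code{"auto"}
#'   (priority InChIKey > ChEBI > BiGG > KEGG, first key present on both
#'   candidates decides), or \code{"id"} (compartment-stripped id).
#' @return list(model, report); report has \code{merged} (data.frame
#'   survivor/removed), \code{zeroed} (reaction, metabolite) entries.
#' @export
deduplicateMetabolites <- function(model, key = "auto") {
  met <- model@metabolites
  known <- names(model@compartments)
  autoOrder <- c("inchikey", "chebi", "bigg.metabolite", "bigg",
                 "kegg.compound", "kegg")
  keyOf <- function(i, db) {
    ann <- met$annotations[[i]]
    names(ann) <- tolower(names(ann))
    if (db == "id") return(metaboliteKey(met$id[i], known))
    v <- ann[[tolower(db)]]
    if (length(v)) v[1] else NA_character_
  }
  groups <- list()
  if (key == "auto") {
    assigned <- rep(FALSE, nrow(met))
    for (db in autoOrder) {
      vals <- vapply(seq_len(nrow(met)), keyOf, "", db = db)
      gk <- paste0(db, "|", vals, "|", met$compartment)
      gk[is.na(vals) | assigned] <- NA
      for (g in unique(stats::na.omit(gk[duplicated(gk) & !is.na(gk)]))) {
        idx <- which(gk == g)
        if (length(idx) > 1L) { groups[[g]] <- idx; assigned[idx] <- TRUE }
      }
    }
  } else {
    vals <- vapply(seq_len(nrow(met)), keyOf, "", db = key)
    gk <- paste0(vals, "|", met$compartment)
    gk[is.na(vals)] <- NA
    for (g in unique(stats::na.omit(gk[duplicated(gk) & !is.na(gk)]))) {
      idx <- which(gk == g)
      if (length(idx) > 1L) groups[[g]] <- idx
    }
  }
  merged <- list(); rename <- character(0); drop <- integer(0)
  for (idx in groups) {
    ids <- met$id[idx]
    survivor <- idx[order(ids)[1]]
    losers <- setdiff(idx, survivor)
    ann <- met$annotations[[survivor]]
    for (l in losers) {
      ann <- unionAnnotations(ann, met$annotations[[l]])
      # conflicting charge/formula: first non-null wins, conflicts kept as-is
      if (is.na(met$charge[survivor]) && !is.na(met$charge[l]))
        met$charge[survivor] <- met$charge[l]
      if (is.na(met$formula[survivor]) && !is.na(met$formula[l]))
        met$formula[survivor] <- met$formula[l]
      rename[met$id[l]] <- met$id[survivor]
      merged[[length(merged) + 1L]] <-
        data.frame(survivor = met$id[survivor], removed = met$id[l],
                   stringsAsFactors = FALSE)
    }
    met$annotations[[survivor]] <- ann
    drop <- c(drop, losers)
  }
  zeroed <- list()
  if (length(drop)) {
    met <- met[-drop, , drop = FALSE]
    rxn <- model@reactions
    for (i in seq_len(nrow(rxn))) {
      s <- rxn$stoich[[i]]
      nm <- names(s)
      hit <- nm %in% names(rename)
      if (!any(hit)) next
      nm[hit] <- unname(rename[nm[hit]])
      s2 <- tapply(s, nm, sum)
      s2 <- stats::setNames(as.numeric(s2), names(s2))
      zero <- names(s2)[s2 == 0]
      for (z in zero)
        zeroed[[length(zeroed) + 1L]] <-
          data.frame(reaction = rxn$id[i], metabolite = z,
                     stringsAsFactors = FALSE)
      rxn$stoich[[i]] <- s2[s2 != 0]
    }
    model@reactions <- rxn
  }
  model@metabolites <- met
  list(model = model,
       report = list(
         merged = if (length(merged)) do.call(rbind, merged) else
           data.frame(survivor = character(0), removed = character(0)),
         zeroed = if (length(zeroed)) do.call(rbind, zeroed) else
           data.frame(reaction = character(0), metabolite = character(0))))
}

#' Check the elemental and charge balance of a reaction
#'
#' Imbalance is the signed sum of coefficient times formula over products
#' and substrates (products minus substrates); generic groups \code{R} and
#' \code{X} are conserved like elements. A participant missing formula or
#' charge makes the report "undetermined" — never treated as balanced.
#'
#' @param reaction reaction id, or a single-row slice of
#'   \code{reactions(model)}.
#' @param model a [GSModel-class].
#' @return a [BalanceReport-class].
#' @examples
#' m <- newModel("w", c(c = "cytosol"))
#' m <- addMetabolite(m, "h2_c", formula = "H2", charge = 0)
#' m <- addMetabolite(m, "o2_c", formula = "O2", charge = 0)
#' m <- addMetabolite(m, "h2o_c", formula = "H2O", charge = 0)
#' m <- addReaction(m, "R1", c(h2_c = -2, o2_c = -1, h2o_c = 2))
#' checkBalance("R1", m)
#' @export
checkBalance <- function(reaction, model) {
  if (is.character(reaction)) {
    i <- reactionRow(model, reaction)
    if (is.na(i)) stop("no such reaction: ", reaction)
    rid <- reaction
    s <- model@reactions$stoich[[i]]
  } else {
    rid <- reaction$id
    s <- reaction$stoich[[1]]
  }
  met <- model@metabolites
  rows <- match(names(s), met$id)
  if (anyNA(rows))
    return(new("BalanceReport", reaction = rid, elementImbalance = numeric(0),
               chargeImbalance = NA_real_, balanced = FALSE, determined = FALSE,
               reason = "unresolved metabolite(s)"))
  noFormula <- names(s)[is.na(met$formula[rows])]
  noCharge <- names(s)[is.na(met$charge[rows])]
  if (length(noFormula) || length(noCharge)) {
    return(new("BalanceReport", reaction = rid, elementImbalance = numeric(0),
               chargeImbalance = NA_real_, balanced = FALSE, determined = FALSE,
               reason = paste0("missing ",
                 paste(c(if (length(noFormula)) paste0("formula: ",
                           paste(noFormula, collapse = ",")),
                         if (length(noCharge)) paste0("charge: ",
                           paste(noCharge, collapse = ","))), collapse = "; "))))
  }
  elem <- formulaSum(met$formula[rows], unname(s))
  chg <- sum(unname(s) * met$charge[rows])
  new("BalanceReport", reaction = rid,
      elementImbalance = elem, chargeImbalance = chg,
      balanced = length(elem) == 0L && chg == 0, determined = TRUE,
      reason = NA_character_)
}
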