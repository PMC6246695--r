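emptyMetaboliteTable <- function() {
  data.frame(id = character(0), name = character(0), compartment = character(0),
             formula = character(0), charge = numeric(0),
             annotations = I(list()), notes = I(list()),
             stringsAsFactors = FALSE)
}

emptyReactionTable <- function() {
  data.frame(id = character(0), lb = numeric(0), ub = numeric(0),
             reversible = logical(0), gene_rule = character(0),
             subsystem = character(0), is_biomass = logical(0),
             is_exchange = logical(0), source = character(0),
             stoich = I(list()), notes = I(list()),
             stringsAsFactors = FALSE)
}

#' Create an empty model
#'
#' @param id model identifier.
#' @param compartments named character vector of compartment ids -> names;
#'   an unnamed vector is used as both id and name. The conventional worm
#'   consensus compartments are cytosol (\code{c}), mitochondrion
#'   (\code{m}), nucleus (\code{n}) and extracellular (\code{e}).
#' @return a [GSModel-class] object.
#' @examples
#' m <- newModel("toy", c(c = "cytosol", e = "extracellular"))
#' m <- addMetabolite(m, "glc__D_c", name = "D-glucose", formula = "C6H12O6",
#'                    charge = 0)
#' @export
newModel <- function(id = "model",
                     compartments = c(c = "cytosol", m = "mitochondrion",
                                      n = "nucleus", e = "extracellular")) {
  if (is.null(names(compartments)))
    names(compartments) <- compartments
  new("GSModel", id = id, compartments = compartments,
      metabolites = emptyMetaboliteTable(), reactions = emptyReactionTable(),
      genes = character(0), objective = NA_character_)
}

#' @describeIn newModel add one metabolite. The compartment defaults to the
#'   trailing \code{_<compartment>} suffix of the id.
#' @param model a [GSModel-class].
#' @param id2 metabolite id (namespaced, compartment-suffixed).
#' @param name display name.
#' @param compartment compartment id; inferred from the id suffix if NULL.
#' @param formula Hill formula string or NA.
#' @param charge integer charge or NA.
#' @param annotations named list of character vectors (database -> ids).
#' @param notes named list.
#' @export
addMetabolite <- function(model, id2, name = id2, compartment = NULL,
                          formula = NA_character_, charge = NA_real_,
                          annotations = list(), notes = list()) {
  if (is.null(compartment)) {
    compartment <- metaboliteCompartment(id2, names(model@compartments))
    if (is.na(compartment))
      stop("cannot infer compartment from id '", id2,
           "'; pass compartment= explicitly")
  }
  row <- data.frame(id = id2, name = name, compartment = compartment,
                    formula = formula, charge = as.numeric(charge),
                    annotations = I(list(annotations)), notes = I(list(notes)),
                    stringsAsFactors = FALSE)
  model@metabolites <- rbind(model@metabolites, row)
  model
}

# trailing-suffix convention: "glc__D_c" -> "c"
metaboliteCompartment <- function(id, known) {
  suf <- sub("^.*_", "", id)
  if (suf %in% known) suf else NA_character_
}

# metabolite key without its compartment suffix ("glc__D_c" -> "glc__D")
metaboliteKey <- function(id, known) {
  comp <- metaboliteCompartment(id, known)
  if (is.na(comp)) id else sub(paste0("_", comp, "$"), "", id)
}

#' @describeIn newModel add one reaction. Stoichiometry is a named numeric
#'   vector (negative = substrate). Default bounds are (-1000, 1000) for
#'   reversible and (0, 1000) for irreversible reactions; a reaction with a
#'   single participant is treated as an exchange reaction unless
#'   \code{is_exchange} is given.
#' @param stoich named numeric vector, metabolite id -> signed coefficient.
#' @param lb,ub flux bounds (mmol/gDW/h convention).
#' @param reversible logical; defaults to \code{lb < 0}.
#' @param gene_rule GPR rule string or NA.
#' @param subsystem pathway/subsystem label.
#' @param is_biomass logical, biomass pseudo-reaction.
#' @param is_exchange logical, boundary pseudo-reaction.
#' @param source provenance tag (model of origin), carried through merges.
#' @export
addReaction <- function(model, id2, stoich, lb = NULL, ub = NULL,
                        reversible = NULL, gene_rule = NA_character_,
                        subsystem = NA_character_, is_biomass = FALSE,
                        is_exchange = NULL, source = NA_character_,
                        notes = list()) {
  stoich <- stoich[stoich != 0]
  if (is.null(reversible)) reversible <- if (!is.null(lb)) lb < 0 else FALSE
  if (is.null(lb)) lb <- if (reversible) -1000 else 0
  if (is.null(ub)) ub <- 1000
  if (is.null(is_exchange)) is_exchange <- length(stoich) == 1L
  if (length(stoich) == 0L && !is_exchange)
    stop("reaction '", id2, "' has empty stoichiometry and is not an exchange")
  newGenes <- gprGenes(gene_rule)
  row <- data.frame(id = id2, lb = lb, ub = ub, reversible = reversible,
                    gene_rule = gene_rule, subsystem = subsystem,
                    is_biomass = is_biomass, is_exchange = is_exchange,
                    source = source,
                    stoich = I(list(stoich)), notes = I(list(notes)),
                    stringsAsFactors = FALSE)
  model@reactions <- rbind(model@reactions, row)
  model@genes <- sort(union(model@genes, newGenes))
  model
}

#' Accessors for GSModel components
#'
#' @param model a [GSModel-class].
#' @return \code{metabolites()} and \code{reactions()} return the underlying
#'   data.frames; \code{genes()}, \code{compartments()},
#'   \code{objectiveReaction()} the respective slots.
#' @name accessors
NULL

#' @rdname accessors
#' @export
metabolites <- function(model) model@metabolites

#' @rdname accessors
#' @export
reactions <- function(model) model@reactions

#' @rdname accessors
#' @export
genes <- function(model) model@genes

#' @rdname accessors
#' @export
compartments <- function(model) model@compartments

#' @rdname accessors
#' @export
objectiveReaction <- function(model) model@objective

#' @rdname accessors
#' @param value replacement value.
#' @export
`objectiveReaction<-` <- function(model, value) {
  model@objective <- as.character(value)
  model
}

#' Validate a model's structural invariants
#'
#' Checks referential integrity (stoichiometry keys resolve, gene-rule
#' leaves declared, compartments declared), id uniqueness, bound sanity and
#' coefficient sanity. Validation never throws; an empty data.frame means
#' every invariant holds.
#'
#' @param model a [GSModel-class].
#' @return data.frame with columns \code{severity} ("error"/"warning"),
#'   \code{code}, \code{subject}, \code{message}.
#' @export
validateModel <- function(model) {
  iss <- list()
  add <- function(severity, code, subject, message)
    iss[[length(iss) + 1L]] <<- data.frame(severity = severity, code = code,
                                           subject = subject, message = message,
                                           stringsAsFactors = FALSE)
  met <- model@metabolites; rxn <- model@reactions
  for (d in unique(met$id[duplicated(met$id)]))
    add("error", "dup_metabolite_id", d, "duplicate metabolite id")
  for (d in unique(rxn$id[duplicated(rxn$id)]))
    add("error", "dup_reaction_id", d, "duplicate reaction id")
  bad <- met$id[!met$compartment %in% names(model@compartments)]
  for (b in bad) add("error", "unknown_compartment", b,
                     "metabolite in undeclared compartment")
  for (i in seq_len(nrow(rxn))) {
    s <- rxn$stoich[[i]]
    missing <- setdiff(names(s), met$id)
    if (length(missing))
      add("error", "unresolved_metabolite", rxn$id[i],
          paste("stoichiometry references missing metabolite(s):",
                paste(missing, collapse = ", ")))
    if (any(s == 0))
      add("error", "zero_coefficient", rxn$id[i], "zero stoichiometric coefficient")
    if (length(s) == 0L && !rxn$is_exchange[i])
      add("error", "empty_stoichiometry", rxn$id[i],
          "non-exchange reaction with empty stoichiometry")
    if (rxn$lb[i] > rxn$ub[i])
      add("error", "bound_order", rxn$id[i], "lower bound exceeds upper bound")
    g <- gprGenes(rxn$gene_rule[i])
    miss <- setdiff(g, model@genes)
    if (length(miss))
      add("error", "undeclared_gene", rxn$id[i],
          paste("gene rule references undeclared gene(s):",
                paste(miss, collapse = ", ")))
  }
  if (!is.na(model@objective) && !(model@objective %in% rxn$id))
    add("error", "missing_objective", model@objective,
        "objective reaction not in model")
  if (length(iss)) do.call(rbind, iss) else
    data.frame(severity = character(0), code = character(0),
               subject = character(0), message = character(0),
               stringsAsFactors = FALSE)
}

# internal: index lookup helpers
metaboliteRow <- function(model, id) match(id, model@metabolites$id)
reactionRow <- function(model, id) match(id, model@reactions$id)

# merge two annotation lists (union per database)
unionAnnotations <- function(a, b) {
  dbs <- union(names(a), names(b))
  out <- lapply(dbs, function(d) sort(unique(c(a[[d]], b[[d]]))))
  stats::setNames(out, dbs)
}

# equality of two models up to annotation ordering; used by round-trip tests
modelEquivalent <- function(a, b, tol = 1e-9) {
  if (!setequal(a@metabolites$id, b@metabolites$id)) return(FALSE)
  if (!setequal(a@reactions$id, b@reactions$id)) return(FALSE)
  if (!setequal(a@genes, b@genes)) return(FALSE)
  ma <- a@metabolites[order(a@metabolites$id), ]
  mb <- b@metabolites[order(b@metabolites$id), ]
  if (!all(ma$compartment == mb$compartment)) return(FALSE)
  fa <- ifelse(is.na(ma$formula), "", ma$formula)
  fb <- ifelse(is.na(mb$formula), "", mb$formula)
  if (!all(fa == fb)) return(FALSE)
  ca <- ifelse(is.na(ma$charge), Inf, ma$charge)
  cb <- ifelse(is.na(mb$charge), Inf, mb$charge)
  if (!all(ca == cb)) return(FALSE)
  ra <- a@reactions[order(a@reactions$id), ]
  rb <- b@reactions[order(b@reactions$id), ]
  for (i in seq_len(nrow(ra))) {
    sa <- ra$stoich[[i]]; sb <- rb$stoich[[i]]
    if (!setequal(names(sa), names(sb))) return(FALSE)
    if (any(abs(sa[names(sa)] - sb[names(sa)]) > tol)) return(FALSE)
    if (abs(ra$lb[i] - rb$lb[i]) > tol || abs(ra$ub[i] - rb$ub[i]) > tol)
      return(FALSE)
    if (!gprEqual(ra$gene_rule[i], rb$gene_rule[i])) return(FALSE)
  }
  for (i in seq_len(nrow(ma))) {
    aa <- ma$annotations[[i]]; ab <- mb$annotations[[i]]
    if (length(aa) + length(ab) == 0L) next
    if (!setequal(names(aa), names(ab))) return(FALSE)
    for (db in names(aa))
      if (!setequal(aa[[db]], ab[[db]])) return(FALSE)
  }
  TRUE
}
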