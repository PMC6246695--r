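SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_L2_NS <- "http://www.sbml.org/sbml/level2/version4"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML SIds must match [A-Za-z_][A-Za-z0-9_]*; COBRA convention prefixes
# M_/R_/G_ and escapes other characters.
sbmlEscape <- function(x) {
  x <- gsub("-", "__45__", x, fixed = TRUE)
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  x
}
sbmlUnescape <- function(x) gsub("__45__", "-", x, fixed = TRUE)

#' Read a constraint-based model from SBML
#'
#' Supports SBML Level 3 with the flux-balance-constraints (FBC) package
#' (bounds as parameters, gene associations as
#' \code{fbc:geneProductAssociation}, objective from \code{fbc:listOfObjectives})
#' and the historical Level 2 COBRA-notes dialect (bounds as kinetic-law
#' parameters \code{LOWER_BOUND}/\code{UPPER_BOUND}, gene rules in
#' \code{GENE_ASSOCIATION:} notes). MIRIAM annotations (identifiers.org
#' URIs) are harvested into \code{prefix -> accession} annotation lists.
#'
#' @param path SBML file.
#' @return a [GSModel-class].
#' @seealso [writeSBML()], [readSBtab()]
#' @export
readSBML <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("not an SBML/XML file: ", path, " (", conditionMessage(e), ")"))
  root <- xml2::xml_ns_strip(doc)  # work namespace-free; fbc attrs keep prefix
  if (xml2::xml_name(root) != "sbml")
    stop("not an SBML file (root element is '", xml2::xml_name(root), "'): ", path)
  mdl <- xml2::xml_find_first(root, "./model")
  level <- xml2::xml_attr(root, "level")

  comps <- xml2::xml_find_all(mdl, "./listOfCompartments/compartment")
  cids <- xml2::xml_attr(comps, "id")
  cnames <- xml2::xml_attr(comps, "name")
  cnames[is.na(cnames)] <- cids[is.na(cnames)]
  model <- newModel(id = xml2::xml_attr(mdl, "id") %||% "model",
                    compartments = stats::setNames(cnames, cids))

  # fbc gene products: sbml-id -> label (fbc-prefixed element names survive
  # namespace stripping, so match on local-name)
  gps <- xml2::xml_find_all(mdl, ".//*[local-name()='geneProduct']")
  gpMap <- character(0)
  if (length(gps)) {
    gpIds <- xml2::xml_attr(gps, "id")
    gpLab <- xml2::xml_attr(gps, "label")
    gpLab[is.na(gpLab)] <- sbmlUnescape(sub("^G_", "", gpIds[is.na(gpLab)]))
    gpMap <- stats::setNames(gpLab, gpIds)
  }

  # global parameters (fbc bound values)
  pars <- xml2::xml_find_all(mdl, "./listOfParameters/parameter")
  parVal <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  spNodes <- xml2::xml_find_all(mdl, "./listOfSpecies/species")
  for (sp in spNodes) {
    sid <- sub("^M_", "", xml2::xml_attr(sp, "id"))
    notes <- sbmlNotesMap(sp)
    formula <- xml2::xml_attr(sp, "chemicalFormula")
    if (is.na(formula)) formula <- notes[["FORMULA"]] %||% NA_character_
    charge <- xml2::xml_attr(sp, "charge")  # fbc:charge (ns-stripped) or L2 charge
    if (is.na(charge)) charge <- notes[["CHARGE"]] %||% NA_character_
    model <- addMetabolite(model, sid,
      name = xml2::xml_attr(sp, "name") %||% sid,
      compartment = xml2::xml_attr(sp, "compartment"),
      formula = if (!is.na(formula) && nzchar(formula)) formula else NA_character_,
      charge = suppressWarnings(as.numeric(charge)),
      annotations = sbmlMiriam(sp),
      notes = notes[setdiff(names(notes), c("FORMULA", "CHARGE"))])
  }

  rxNodes <- xml2::xml_find_all(mdl, "./listOfReactions/reaction")
  unresolved <- character(0)
  metIds <- model@metabolites$id
  for (rx in rxNodes) {
    rid <- sub("^R_", "", xml2::xml_attr(rx, "id"))
    stoich <- numeric(0)
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rx, paste0("./", tag, "/speciesReference"))
      for (ref in refs) {
        sid <- sub("^M_", "", xml2::xml_attr(ref, "species"))
        co <- as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
        if (!(sid %in% metIds)) unresolved <- c(unresolved, sid)
        stoich[sid] <- (stoich[sid] %||% 0) + side * co
      }
    }
    rev <- !identical(xml2::xml_attr(rx, "reversible"), "false")
    notes <- sbmlNotesMap(rx)
    # bounds: FBC attributes referencing parameters, else kinetic-law parameters
    lbRef <- xml2::xml_attr(rx, "lowerFluxBound")
    ubRef <- xml2::xml_attr(rx, "upperFluxBound")
    lb <- if (!is.na(lbRef)) unname(parVal[lbRef]) else sbmlKineticParam(rx, "LOWER_BOUND")
    ub <- if (!is.na(ubRef)) unname(parVal[ubRef]) else sbmlKineticParam(rx, "UPPER_BOUND")
    # gene association: FBC subtree, else notes
    gpa <- xml2::xml_find_first(rx, "./*[local-name()='geneProductAssociation']")
    rule <- if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) gprFormat(gprCanonicalize(sbmlGpaTree(kids[[1]], gpMap)))
      else NA_character_
    } else notes[["GENE_ASSOCIATION"]] %||% NA_character_
    subsystem <- notes[["SUBSYSTEM"]] %||% NA_character_
    model <- addReaction(model, rid, stoich,
      lb = if (is.na(lb %||% NA)) NULL else lb,
      ub = if (is.na(ub %||% NA)) NULL else ub,
      reversible = rev, gene_rule = rule, subsystem = subsystem,
      is_biomass = isTRUE(tolower(notes[["BIOMASS"]] %||% "") == "true") ||
        grepl("biomass", rid, ignore.case = TRUE),
      notes = notes[setdiff(names(notes),
                            c("GENE_ASSOCIATION", "SUBSYSTEM", "BIOMASS"))])
  }
  if (length(unresolved))
    stop("integrity error: unresolvable species reference(s): ",
         paste(unique(unresolved), collapse = ", "))

  # objective: FBC active objective, else notes marker, else biomass flag
  fluxObj <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  if (!inherits(fluxObj, "xml_missing")) {
    model@objective <- sub("^R_", "", xml2::xml_attr(fluxObj, "reaction"))
  } else {
    bm <- model@reactions$id[model@reactions$is_biomass]
    if (length(bm)) model@objective <- bm[1]
  }
  validObject(model)
  model
}

# "<p>KEY: value</p>" entries within an element's notes
sbmlNotesMap <- function(node) {
  ps <- xml2::xml_find_all(node, "./notes//p | ./notes//*[local-name()='p']")
  out <- list()
  for (p in ps) {
    txt <- xml2::xml_text(p)
    if (grepl(":", txt, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", txt))
      val <- trimws(sub("^[^:]*:", "", txt))
      out[[key]] <- val
    }
  }
  out
}

sbmlKineticParam <- function(rx, pid) {
  p <- xml2::xml_find_first(rx, paste0(
    "./kineticLaw/listOfParameters/parameter[@id='", pid, "']"))
  if (inherits(p, "xml_missing")) NA_real_
  else as.numeric(xml2::xml_attr(p, "value"))
}

# identifiers.org URIs -> list(prefix = accessions)
sbmlMiriam <- function(node) {
  lis <- xml2::xml_find_all(node, ".//*[local-name()='li']")
  out <- list()
  for (li in lis) {
    uri <- xml2::xml_attr(li, "resource")
    if (is.na(uri)) next
    rest <- sub("^https?://identifiers\\.org/", "", uri)
    if (identical(rest, uri)) next
    db <- sub("/.*$", "", rest)
    acc <- sub("^[^/]*/", "", rest)
    out[[db]] <- c(out[[db]], acc)
  }
  lapply(out, function(v) sort(unique(v)))
}

# FBC geneProductAssociation subtree -> gpr tree
sbmlGpaTree <- function(node, gpMap) {
  nm <- sub("^.*:", "", xml2::xml_name(node))
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    return(unname(gpMap[ref] %||% sbmlUnescape(sub("^G_", "", ref))))
  }
  kids <- xml2::xml_children(node)
  list(op = if (nm == "and") "and" else "or",
       args = lapply(kids, sbmlGpaTree, gpMap = gpMap))
}

#' Write a model to SBML
#'
#' @param model a [GSModel-class]; must pass [validateModel()] with no
#'   errors (dangling references are refused).
#' @param path output file.
#' @param level 3 (default; FBC for bounds, objective and gene rules) or 2
#'   (COBRA dialect: bounds as kinetic-law parameters, GPR and formula/charge
#'   in notes).
#' @return the path, invisibly.
#' @export
writeSBML <- function(model, path, level = 3) {
  iss <- validateModel(model)
  if (any(iss$severity == "error"))
    stop("refusing to write invalid model: ",
         paste(unique(iss$code), collapse = ", "))
  if (level == 3) writeSBML3(model, path) else writeSBML2(model, path)
  invisible(path)
}

xmlq <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

sbmlAnnotationXML <- function(id, ann, indent) {
  if (length(ann) == 0L) return(character(0))
  uris <- unlist(lapply(names(ann), function(db)
    paste0("http://identifiers.org/", db, "/", ann[[db]])))
  c(paste0(indent, "<annotation>"),
    paste0(indent, ' <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">'),
    paste0(indent, '  <rdf:Description rdf:about="#', id, '">'),
    paste0(indent, "   <bqbiol:is><rdf:Bag>"),
    paste0(indent, '    <rdf:li rdf:resource="', xmlq(uris), '"/>'),
    paste0(indent, "   </rdf:Bag></bqbiol:is>"),
    paste0(indent, "  </rdf:Description>"),
    paste0(indent, " </rdf:RDF>"),
    paste0(indent, "</annotation>"))
}

sbmlNotesXML <- function(kv, indent) {
  kv <- kv[!vapply(kv, function(v) is.null(v) || is.na(v) || !nzchar(v), TRUE)]
  if (length(kv) == 0L) return(character(0))
  c(paste0(indent, "<notes>"),
    paste0(indent, ' <body xmlns="http://www.w3.org/1999/xhtml">'),
    paste0(indent, "  <p>", xmlq(names(kv)), ": ", xmlq(unlist(kv)), "</p>"),
    paste0(indent, " </body>"),
    paste0(indent, "</notes>"))
}

speciesRefsXML <- function(stoich, side) {
  part <- stoich[sign(stoich) == side]
  if (length(part) == 0L) return(character(0))
  tag <- if (side < 0) "listOfReactants" else "listOfProducts"
  c(paste0("      <", tag, ">"),
    vapply(seq_along(part), function(i) paste0(
      '        <speciesReference species="M_', names(part)[i],
      '" stoichiometry="', formatCoefficient(abs(part[i])),
      '" constant="true"/>'), ""),
    paste0("      </", tag, ">"))
}

gprFbcXML <- function(rule, geneIdOf) {
  dnf <- gprCanonicalize(rule)
  if (length(dnf) == 0L) return(character(0))
  termXML <- function(s, ind) {
    if (length(s) == 1L)
      return(paste0(ind, '<fbc:geneProductRef fbc:geneProduct="', geneIdOf(s), '"/>'))
    c(paste0(ind, "<fbc:and>"),
      vapply(s, function(g) paste0(ind, ' <fbc:geneProductRef fbc:geneProduct="',
                                   geneIdOf(g), '"/>'), ""),
      paste0(ind, "</fbc:and>"))
  }
  if (length(dnf) == 1L) {
    c("      <fbc:geneProductAssociation>",
      termXML(dnf[[1]], "        "),
      "      </fbc:geneProductAssociation>")
  } else {
    c("      <fbc:geneProductAssociation>",
      "        <fbc:or>",
      unlist(lapply(dnf, termXML, ind = "          ")),
      "        </fbc:or>",
      "      </fbc:geneProductAssociation>")
  }
}

writeSBML3 <- function(model, path) {
  met <- model@metabolites; rxn <- model@reactions
  geneIdOf <- function(g) paste0("G_", sbmlEscape(g))
  # distinct bound parameters
  bvals <- sort(unique(c(rxn$lb, rxn$ub)))
  bid <- function(v) paste0("fb_", sbmlEscape(formatCoefficient(v)))
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_L3_NS, '" xmlns:fbc="', FBC_NS,
           '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', sbmlEscape(model@id), '" fbc:strict="true">'),
    "    <listOfCompartments>",
    vapply(seq_along(model@compartments), function(i) paste0(
      '      <compartment id="', names(model@compartments)[i], '" name="',
      xmlq(model@compartments[i]), '" constant="true"/>'), ""),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (i in seq_len(nrow(met))) {
    attrs <- paste0('id="M_', met$id[i], '" name="', xmlq(met$name[i]),
                    '" compartment="', met$compartment[i],
                    '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"')
    if (!is.na(met$formula[i]))
      attrs <- paste0(attrs, ' fbc:chemicalFormula="', met$formula[i], '"')
    if (!is.na(met$charge[i]))
      attrs <- paste0(attrs, ' fbc:charge="', formatCoefficient(met$charge[i]), '"')
    ann <- met$annotations[[i]]
    if (length(ann) || length(met$notes[[i]])) {
      out <- c(out, paste0("      <species ", attrs, ">"),
               sbmlNotesXML(met$notes[[i]], "        "),
               sbmlAnnotationXML(paste0("M_", met$id[i]), ann, "        "),
               "      </species>")
    } else {
      out <- c(out, paste0("      <species ", attrs, "/>"))
    }
  }
  out <- c(out, "    </listOfSpecies>",
    "    <listOfParameters>",
    vapply(bvals, function(v) paste0(
      '      <parameter id="', bid(v), '" value="', formatCoefficient(v),
      '" constant="true"/>'), ""),
    "    </listOfParameters>",
    "    <listOfReactions>")
  for (i in seq_len(nrow(rxn))) {
    hdr <- paste0('      <reaction id="R_', rxn$id[i], '" reversible="',
                  tolower(rxn$reversible[i]), '" fast="false" fbc:lowerFluxBound="',
                  bid(rxn$lb[i]), '" fbc:upperFluxBound="', bid(rxn$ub[i]), '">')
    notes <- rxn$notes[[i]]
    if (!is.na(rxn$subsystem[i])) notes[["SUBSYSTEM"]] <- rxn$subsystem[i]
    if (rxn$is_biomass[i]) notes[["BIOMASS"]] <- "true"
    out <- c(out, hdr,
             sbmlNotesXML(notes, "        "),
             gprFbcXML(rxn$gene_rule[i], geneIdOf),
             speciesRefsXML(rxn$stoich[[i]], -1),
             speciesRefsXML(rxn$stoich[[i]], +1),
             "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>")
  if (!is.na(model@objective)) {
    out <- c(out,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      "        <fbc:listOfFluxObjectives>",
      paste0('          <fbc:fluxObjective fbc:reaction="R_', model@objective,
             '" fbc:coefficient="1"/>'),
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }
  if (length(model@genes)) {
    out <- c(out, "    <fbc:listOfGeneProducts>",
      vapply(model@genes, function(g) paste0(
        '      <fbc:geneProduct fbc:id="', geneIdOf(g), '" fbc:label="',
        xmlq(g), '"/>'), ""),
      "    </fbc:listOfGeneProducts>")
  }
  out <- c(out, "  </model>", "</sbml>")
  writeLines(out, path, useBytes = TRUE)
}

writeSBML2 <- function(model, path) {
  met <- model@metabolites; rxn <- model@reactions
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_L2_NS, '" level="2" version="4">'),
    paste0('  <model id="', sbmlEscape(model@id), '">'),
    "    <listOfCompartments>",
    vapply(seq_along(model@compartments), function(i) paste0(
      '      <compartment id="', names(model@compartments)[i], '" name="',
      xmlq(model@compartments[i]), '"/>'), ""),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (i in seq_len(nrow(met))) {
    notes <- met$notes[[i]]
    if (!is.na(met$formula[i])) notes[["FORMULA"]] <- met$formula[i]
    if (!is.na(met$charge[i])) notes[["CHARGE"]] <- formatCoefficient(met$charge[i])
    out <- c(out,
      paste0('      <species id="M_', met$id[i], '" name="', xmlq(met$name[i]),
             '" compartment="', met$compartment[i], '">'),
      sbmlNotesXML(notes, "        "),
      sbmlAnnotationXML(paste0("M_", met$id[i]), met$annotations[[i]], "        "),
      "      </species>")
  }
  out <- c(out, "    </listOfSpecies>", "    <listOfReactions>")
  for (i in seq_len(nrow(rxn))) {
    notes <- rxn$notes[[i]]
    if (!is.na(rxn$gene_rule[i])) notes[["GENE_ASSOCIATION"]] <- rxn$gene_rule[i]
    if (!is.na(rxn$subsystem[i])) notes[["SUBSYSTEM"]] <- rxn$subsystem[i]
    if (rxn$is_biomass[i]) notes[["BIOMASS"]] <- "true"
    out <- c(out,
      paste0('      <reaction id="R_', rxn$id[i], '" reversible="',
             tolower(rxn$reversible[i]), '">'),
      sbmlNotesXML(notes, "        "),
      speciesRefsXML2(rxn$stoich[[i]], -1),
      speciesRefsXML2(rxn$stoich[[i]], +1),
      "        <kineticLaw>",
      "          <math xmlns=\"http://www.w3.org/1998/Math/MathML\"><ci> FLUX_VALUE </ci></math>",
      "          <listOfParameters>",
      paste0('            <parameter id="LOWER_BOUND" value="',
             formatCoefficient(rxn$lb[i]), '" units="mmol_per_gDW_per_hr"/>'),
      paste0('            <parameter id="UPPER_BOUND" value="',
             formatCoefficient(rxn$ub[i]), '" units="mmol_per_gDW_per_hr"/>'),
      paste0('            <parameter id="OBJECTIVE_COEFFICIENT" value="',
             if (identical(model@objective, rxn$id[i])) "1" else "0", '"/>'),
      "          </listOfParameters>",
      "        </kineticLaw>",
      "      </reaction>")
  }
  c(out, "    </listOfReactions>", "  </model>", "</sbml>") |>
    writeLines(path, useBytes = TRUE)
}

speciesRefsXML2 <- function(stoich, side) {
  part <- stoich[sign(stoich) == side]
  if (length(part) == 0L) return(character(0))
  tag <- if (side < 0) "listOfReactants" else "listOfProducts"
  c(paste0("        <", tag, ">"),
    vapply(seq_along(part), function(i) paste0(
      '          <speciesReference species="M_', names(part)[i],
      '" stoichiometry="', formatCoefficient(abs(part[i])), '"/>'), ""),
    paste0("        </", tag, ">"))
}
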