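#' Read and write models as SBtab spreadsheets
#'
#' SBtab is a tab-separated convention for exchanging systems-biology
#' models as human-editable tables. The dialect written here has one
#' \code{!!SBtab} declaration line per table followed by a \code{!}-prefixed
#' column header; the Reaction and Compound tables are mandatory, a Gene
#' table is emitted when the model has genes. Reaction equations use arrow
#' notation (\code{"A + 2 B <=> C"}; \code{<=>} reversible, \code{=>}
#' irreversible).
#'
#' @param path file path of a tab-delimited UTF-8 SBtab document.
#' @return \code{readSBtab()}: a [GSModel-class].
#' @examples
#' m <- newModel("toy", c(c = "cytosol"))
#' m <- addMetabolite(m, "A_c")
#' m <- addMetabolite(m, "B_c")
#' m <- addReaction(m, "R1", c(A_c = -1, B_c = 1))
#' f <- tempfile(fileext = ".tsv")
#' writeSBtab(m, f)
#' m2 <- readSBtab(f)
#' @export
readSBtab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  decl <- grep("^!!SBtab", lines)
  if (length(decl) == 0L) stop("not an SBtab file (no !!SBtab declaration): ", path)
  tables <- list()
  bounds <- c(decl, length(lines) + 1L)
  for (k in seq_along(decl)) {
    hdr <- lines[decl[k]]
    tname <- sub('.*TableName=(\'[^\']*\'|"[^"]*"|[^\t ]+).*', "\\1", hdr)
    tname <- gsub("['\"]", "", tname)
    block <- lines[(decl[k] + 1L):(bounds[k + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    if (length(block) == 0L) { tables[[tname]] <- NULL; next }
    cols <- strsplit(block[1], "\t", fixed = TRUE)[[1]]
    cols <- sub("^!", "", cols)
    rows <- if (length(block) > 1L)
      do.call(rbind, lapply(strsplit(block[-1], "\t", fixed = TRUE), function(x) {
        length(x) <- length(cols); x
      })) else matrix(character(0), 0, length(cols))
    df <- as.data.frame(rows, stringsAsFactors = FALSE)
    names(df) <- cols
    tables[[tname]] <- df
  }
  for (req in c("Reaction", "Compound")) {
    if (is.null(tables[[req]]) && !(req %in% names(tables)))
      stop("SBtab schema error: mandatory table '", req, "' missing")
  }
  cmp <- tables[["Compound"]]
  if (is.null(cmp)) cmp <- data.frame(ID = character(0))
  if (!"ID" %in% names(cmp))
    stop("SBtab schema error: table 'Compound' lacks mandatory column 'ID'")
  rx <- tables[["Reaction"]]
  if (is.null(rx)) rx <- data.frame(ID = character(0), ReactionFormula = character(0))
  for (col in c("ID", "ReactionFormula"))
    if (!col %in% names(rx))
      stop("SBtab schema error: table 'Reaction' lacks mandatory column '", col, "'")

  comps <- unique(stats::na.omit(if ("Compartment" %in% names(cmp))
    cmp$Compartment else character(0)))
  comps <- comps[nzchar(comps)]
  if (length(comps) == 0L) comps <- "c"
  model <- newModel(id = sub("[.][^.]*$", "", basename(path)),
                    compartments = stats::setNames(comps, comps))
  numOrNA <- function(x) suppressWarnings(as.numeric(x))
  for (i in seq_len(nrow(cmp))) {
    comp <- if ("Compartment" %in% names(cmp) && nzchar(cmp$Compartment[i]))
      cmp$Compartment[i] else comps[1]
    ann <- list()
    if ("Identifiers" %in% names(cmp) && nzchar(cmp$Identifiers[i] %||% ""))
      ann <- parseAnnotationField(cmp$Identifiers[i])
    model <- addMetabolite(model, cmp$ID[i],
      name = if ("Name" %in% names(cmp) && nzchar(cmp$Name[i] %||% "")) cmp$Name[i] else cmp$ID[i],
      compartment = comp,
      formula = if ("Formula" %in% names(cmp) && nzchar(cmp$Formula[i] %||% "")) cmp$Formula[i] else NA_character_,
      charge = if ("Charge" %in% names(cmp)) numOrNA(cmp$Charge[i]) else NA_real_,
      annotations = ann)
  }
  for (i in seq_len(nrow(rx))) {
    eq <- parseReactionEquation(rx$ReactionFormula[i])
    lb <- if ("LowerBound" %in% names(rx)) numOrNA(rx$LowerBound[i]) else NA_real_
    ub <- if ("UpperBound" %in% names(rx)) numOrNA(rx$UpperBound[i]) else NA_real_
    model <- addReaction(model, rx$ID[i], eq$stoich,
      lb = if (is.na(lb)) NULL else lb, ub = if (is.na(ub)) NULL else ub,
      reversible = eq$reversible,
      gene_rule = if ("GeneAssociation" %in% names(rx) && nzchar(rx$GeneAssociation[i] %||% ""))
        rx$GeneAssociation[i] else NA_character_,
      subsystem = if ("Subsystem" %in% names(rx) && nzchar(rx$Subsystem[i] %||% ""))
        rx$Subsystem[i] else NA_character_,
      is_biomass = "IsBiomass" %in% names(rx) && tolower(rx$IsBiomass[i] %||% "") %in% c("true", "1"),
      source = if ("Source" %in% names(rx) && nzchar(rx$Source[i] %||% ""))
        rx$Source[i] else NA_character_)
  }
  if (!is.null(tables[["Gene"]]) && "ID" %in% names(tables[["Gene"]])) {
    model@genes <- sort(union(model@genes, tables[["Gene"]]$ID))
  }
  obj <- model@reactions$id[model@reactions$is_biomass]
  if (length(obj)) model@objective <- obj[1]
  validObject(model)
  model
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

# "2 A_c + B_c <=> 0.5 C_c" -> list(stoich=..., reversible=...)
parseReactionEquation <- function(eq) {
  eq <- trimws(eq)
  rev <- grepl("<=>", eq, fixed = TRUE)
  sides <- if (rev) strsplit(eq, "<=>", fixed = TRUE)[[1]]
    else strsplit(eq, "=>", fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parseSide <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (t in terms[nzchar(terms)]) {
      p <- strsplit(t, "[[:space:]]+")[[1]]
      if (length(p) == 2L) {
        out[p[2]] <- (out[p[2]] %||% 0) + sign * as.numeric(p[1])
      } else {
        out[p[1]] <- (out[p[1]] %||% 0) + sign
      }
    }
    out
  }
  s <- c(parseSide(sides[1], -1), parseSide(sides[2], +1))
  # same metabolite on both sides: sum
  s <- tapply(s, names(s), sum)
  s <- stats::setNames(as.numeric(s), names(s))
  list(stoich = s[s != 0], reversible = rev)
}

formatReactionEquation <- function(stoich, reversible) {
  fmtSide <- function(v) {
    if (length(v) == 0L) return("")
    paste(vapply(seq_along(v), function(i) {
      co <- abs(v[i])
      if (co == 1) names(v)[i] else paste(formatCoefficient(co), names(v)[i])
    }, ""), collapse = " + ")
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(fmtSide(lhs), if (reversible) "<=>" else "=>", fmtSide(rhs))
}

# shortest decimal that round-trips (up to 15 significant digits)
formatCoefficient <- function(x) {
  for (d in 1:15) {
    s <- trimws(format(x, digits = d, scientific = FALSE))
    if (as.numeric(s) == x) return(s)
  }
  trimws(format(x, digits = 17))
}

# "chebi:CHEBI:18237;kegg.compound:C00025" -> list(chebi=..., kegg.compound=...)
parseAnnotationField <- function(x) {
  out <- list()
  for (item in strsplit(x, ";", fixed = TRUE)[[1]]) {
    item <- trimws(item)
    if (!nzchar(item)) next
    db <- sub(":.*$", "", item)
    acc <- sub("^[^:]*:", "", item)
    out[[db]] <- c(out[[db]], acc)
  }
  out
}

formatAnnotationField <- function(ann) {
  if (length(ann) == 0L) return("")
  paste(unlist(lapply(names(ann), function(db)
    paste0(db, ":", ann[[db]]))), collapse = ";")
}

#' @rdname readSBtab
#' @param model a [GSModel-class] to serialize.
#' @return \code{writeSBtab()}: the path, invisibly.
#' @export
writeSBtab <- function(model, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con, useBytes = FALSE)
  doc <- model@id
  met <- model@metabolites
  writeLines(sprintf(
    "!!SBtab TableID='compound' TableType='Compound' TableName='Compound' Document='%s'",
    doc), con)
  w(paste(c("!ID", "!Name", "!Compartment", "!Formula", "!Charge",
            "!Identifiers"), collapse = "\t"))
  for (i in seq_len(nrow(met))) {
    w(paste(c(met$id[i], met$name[i], met$compartment[i],
              met$formula[i] %||% "",
              if (is.na(met$charge[i])) "" else formatCoefficient(met$charge[i]),
              formatAnnotationField(met$annotations[[i]])), collapse = "\t"))
  }
  rxn <- model@reactions
  writeLines(sprintf(
    "!!SBtab TableID='reaction' TableType='Reaction' TableName='Reaction' Document='%s'",
    doc), con)
  w(paste(c("!ID", "!ReactionFormula", "!GeneAssociation", "!LowerBound",
            "!UpperBound", "!Subsystem", "!IsBiomass", "!Source"), collapse = "\t"))
  for (i in seq_len(nrow(rxn))) {
    w(paste(c(rxn$id[i],
              formatReactionEquation(rxn$stoich[[i]], rxn$reversible[i]),
              rxn$gene_rule[i] %||% "",
              formatCoefficient(rxn$lb[i]), formatCoefficient(rxn$ub[i]),
              rxn$subsystem[i] %||% "",
              if (rxn$is_biomass[i]) "True" else "False",
              rxn$source[i] %||% ""), collapse = "\t"))
  }
  if (length(model@genes)) {
    writeLines(sprintf(
      "!!SBtab TableID='gene' TableType='Gene' TableName='Gene' Document='%s'",
      doc), con)
    w("!ID")
    for (g in model@genes) w(g)
  }
  invisible(path)
}
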