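#' InChIKey connectivity block
#'
#' The first 14-character block of an InChIKey hashes the atom-connectivity
#' layer only, so stereoisomers and protonation states share a block —
#' e.g. beta-D-glucose 6-phosphate and beta-D-galactose 6-phosphate
#' collapse to one entity. This is the identity used for model-vs-detected
#' metabolite comparison.
#'
#' @param inchikey character vector of 27-character InChIKeys
#'   (\code{XXXXXXXXXXXXXX-YYYYYYYYFV-P}).
#' @return character vector of 14-character connectivity keys.
#' @examples
#' inchikeyBlock1("NBSCHQHZLSJFNQ-FPRJBGLDSA-N")
#' @export
inchikeyBlock1 <- function(inchikey) {
  ok <- grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", inchikey)
  if (any(!ok))
    stop("malformed InChIKey(s): ",
         paste(inchikey[!ok], collapse = ", "))
  substr(inchikey, 1L, 14L)
}

#' Build a structure-record table
#'
#' One row per metabolite structure, from the model side or the
#' detected-in-literature side. Missing identifier fields are completed
#' where derivable: InChIKey from SMILES or InChI through Open Babel.
#' Generic structures (R-group formulas, no concrete SMILES/InChI) keep
#' their formula but are excluded from fingerprints and entity keys.
#'
#' @param path TSV with header; recognized columns: \code{id}, \code{name},
#'   \code{inchi}, \code{inchikey}, \code{smiles}, \code{formula},
#'   \code{charge}, \code{xrefs}, \code{source}, \code{detection_count}.
#' @return data.frame of structure records.
#' @export
readStructureTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "")
  if (!"id" %in% names(df))
    stop("structure table schema error: missing column 'id'")
  for (col in c("name", "inchi", "inchikey", "smiles", "formula", "source"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  df$charge <- if ("charge" %in% names(df))
    suppressWarnings(as.numeric(df$charge)) else NA_real_
  df$detection_count <- if ("detection_count" %in% names(df))
    suppressWarnings(as.integer(df$detection_count)) else NA_integer_
  bad <- !is.na(df$inchikey) &
    !grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", df$inchikey)
  if (any(bad))
    stop("malformed InChIKey(s) in structure table: ",
         paste(df$inchikey[bad], collapse = ", "))
  df
}

#' Complete InChIKeys from SMILES/InChI
#'
#' @param records structure-record data.frame.
#' @return records with \code{inchikey} filled where derivable.
#' @export
deriveInchikeys <- function(records) {
  need <- which(is.na(records$inchikey) & !is.na(records$smiles))
  if (length(need)) {
    keys <- smilesToInchikey(records$smiles[need])
    ok <- !is.na(keys)
    records$inchikey[need[ok]] <- keys[ok]
  }
  records
}

# vectorized SMILES -> InChIKey via Open Babel; NA for unparseable input
smilesToInchikey <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  idx <- which(!is.na(smiles) & nzchar(smiles))
  if (length(idx) == 0L) return(out)
  res <- tryCatch(
    ChemmineOB::convertFormat("SMI", "INCHIKEY",
                              source = paste(smiles[idx], collapse = "\n")),
    error = function(e) NA_character_)
  keys <- strsplit(res %||% "", "\n")[[1]]
  keys <- trimws(keys[nzchar(trimws(keys))])
  if (length(keys) == length(idx)) {
    out[idx] <- keys
  } else {
    # length mismatch (some molecules failed): fall back to one-by-one
    for (i in idx) {
      k <- tryCatch(trimws(ChemmineOB::convertFormat("SMI", "INCHIKEY",
                                                     source = smiles[i])),
                    error = function(e) "")
      if (grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", k)) out[i] <- k
    }
  }
  out[!grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", out)] <- NA_character_
  out
}

#' Path-based structure fingerprints
#'
#' 1024-bit path-based fingerprints (Open Babel FP2: linear fragments up to
#' seven atoms, hashed) computed from SMILES; independent of SMILES
#' writing order because the structure is canonicalized on parsing.
#'
#' @param records structure-record data.frame (needs a parseable
#'   \code{smiles}; records without one error in single mode and are
#'   skipped with a warning in batch mode).
#' @param batch skip unparseable records instead of erroring.
#' @return logical matrix, one row per fingerprinted record, rownames =
#'   record ids; attribute \code{"skipped"} lists skipped ids.
#' @export
fingerprintStructures <- function(records, batch = TRUE) {
  fps <- list(); skipped <- character(0)
  for (i in seq_len(nrow(records))) {
    smi <- records$smiles[i]
    if (is.na(smi) || !nzchar(smi) || grepl("\\*", smi)) {
      # generic (R-group) or absent structure
      if (!batch) stop("record '", records$id[i],
                       "' has no fingerprintable structure")
      skipped <- c(skipped, records$id[i]); next
    }
    fp <- tryCatch(
      as.logical(ChemmineOB::fingerprint_OB(
        ChemmineOB::forEachMol("SMILES", smi, identity), "FP2")),
      error = function(e) NULL)
    if (is.null(fp) || length(fp) != 1024L || !any(fp)) {
      if (!batch) stop("unparseable structure for record '",
                       records$id[i], "': ", smi)
      skipped <- c(skipped, records$id[i]); next
    }
    fps[[records$id[i]]] <- fp
  }
  m <- if (length(fps)) do.call(rbind, fps) else
    matrix(logical(0), 0, 1024)
  attr(m, "skipped") <- skipped
  m
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{|a \wedge b| / |a \vee b|}; defined as 0 when both fingerprints are
#' empty.
#'
#' @param a,b logical vectors of equal length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Similarity configuration
#'
#' @param cutoff Tanimoto cutoff above which a pair counts as structurally
#'   related (default 0.4; fingerprint-dependent, hence tunable).
#' @param hub_exclusions metabolite keys excluded from reaction-pair
#'   foregrounds — the currency metabolites (water, protons, nucleotide
#'   cofactors, CoA, redox carriers, phosphates) that would otherwise
#'   dominate substrate-product pairs.
#' @param background_sample_size sample size for the all-pairs background
#'   distribution when the combinatorial set is larger (seeded by the
#'   caller via set.seed).
#' @export
similarityConfig <- function(cutoff = 0.4,
                             hub_exclusions = c(
                               "h2o", "h", "atp", "adp", "amp", "coa",
                               "nad", "nadh", "nadp", "nadph", "fad",
                               "fadh2", "pi", "ppi", "co2", "udp", "utp"),
                             background_sample_size = 100000L) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  structure(list(cutoff = cutoff, hub_exclusions = hub_exclusions,
                 background_sample_size = background_sample_size),
            class = "similarityConfig")
}

#' Calibrate the similarity cutoff from reaction pairs
#'
#' Foreground: Tanimoto similarities of substrate-product pairs across all
#' model reactions, hub metabolites removed. Background: all (or sampled)
#' unordered structure pairs. Reaction neighbors are structurally close, so
#' the foreground should dominate the background; the default cutoff 0.4
#' is returned unless \code{rule = "density"}, which returns the smallest
#' grid point where the foreground density exceeds the background density.
#'
#' @param model a [GSModel-class].
#' @param records structure records covering model metabolites (matched by
#'   compartment-stripped metabolite key against \code{records$id}).
#' @param config a [similarityConfig()].
#' @param rule \code{"default"} or \code{"density"}.
#' @return list(foreground, background, cutoff).
#' @export
calibrateCutoff <- function(model, records, config = similarityConfig(),
                            rule = c("default", "density")) {
  rule <- match.arg(rule)
  fps <- fingerprintStructures(records)
  known <- names(model@compartments)
  pairs <- list()
  for (i in seq_len(nrow(model@reactions))) {
    s <- model@reactions$stoich[[i]]
    keys <- vapply(names(s), metaboliteKey, "", known = known)
    keep <- !(keys %in% config$hub_exclusions)
    subs <- unique(keys[s < 0 & keep]); prods <- unique(keys[s > 0 & keep])
    for (a in subs) for (b in prods)
      if (a != b) pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  have <- rownames(fps)
  fg <- vapply(pairs, function(p) {
    if (all(p %in% have)) tanimoto(fps[p[1], ], fps[p[2], ]) else NA_real_
  }, 0)
  fg <- fg[!is.na(fg)]
  if (length(fg) == 0L)
    stop("empty foreground: no fingerprinted substrate-product pairs")
  n <- nrow(fps)
  allPairs <- utils::combn(n, 2)
  if (ncol(allPairs) > config$background_sample_size)
    allPairs <- allPairs[, sample.int(ncol(allPairs),
                                      config$background_sample_size)]
  bg <- vapply(seq_len(ncol(allPairs)), function(k)
    tanimoto(fps[allPairs[1, k], ], fps[allPairs[2, k], ]), 0)
  cutoff <- config$cutoff
  if (rule == "density" && length(bg) > 1L && length(fg) > 1L) {
    grid <- seq(0, 1, by = 0.01)
    dfg <- stats::density(fg, from = 0, to = 1, n = length(grid))$y
    dbg <- stats::density(bg, from = 0, to = 1, n = length(grid))$y
    above <- which(dfg > dbg & grid > 0)
    if (length(above)) cutoff <- grid[min(above)]
  }
  list(foreground = fg, background = bg, cutoff = cutoff)
}

#' Entity coverage of detected metabolites by the model
#'
#' Partitions InChIKey connectivity-block entities into overlap,
#' model-only and detected-only. Records without a key are counted
#' separately and excluded from the partition.
#'
#' @param modelRecords,detectedRecords structure-record data.frames.
#' @return a [CoverageReport-class].
#' @export
coverage <- function(modelRecords, detectedRecords) {
  keyize <- function(rec) {
    keys <- rec$inchikey[!is.na(rec$inchikey)]
    list(entities = unique(inchikeyBlock1(keys)),
         nokey = sum(is.na(rec$inchikey)))
  }
  m <- keyize(modelRecords); d <- keyize(detectedRecords)
  new("CoverageReport",
      nModelEntities = length(m$entities),
      nDetectedEntities = length(d$entities),
      overlap = sort(intersect(m$entities, d$entities)),
      modelOnly = sort(setdiff(m$entities, d$entities)),
      detectedOnly = sort(setdiff(d$entities, m$entities)),
      nModelNoKey = as.integer(m$nokey),
      nDetectedNoKey = as.integer(d$nokey))
}

#' Nearest model neighbors for detected-only metabolites
#'
#' For each detected metabolite absent from the model, ranks model
#' structures with Tanimoto similarity above the cutoff — candidate
#' connection points of unmapped metabolites to existing pathways (e.g.
#' methylated nucleosides next to their parent nucleoside).
#'
#' @param detectedRecords,modelRecords structure-record data.frames.
#' @param config a [similarityConfig()].
#' @return data.frame (query_id, model_id, tanimoto), sorted per query by
#'   descending similarity; zero rows when nothing clears the cutoff.
#' @export
nearestModelNeighbors <- function(detectedRecords, modelRecords,
                                  config = similarityConfig()) {
  fpd <- fingerprintStructures(detectedRecords)
  fpm <- fingerprintStructures(modelRecords)
  out <- list()
  for (q in rownames(fpd)) {
    sims <- vapply(rownames(fpm), function(m2)
      tanimoto(fpd[q, ], fpm[m2, ]), 0)
    sims <- sims[sims > config$cutoff]
    if (length(sims) == 0L) next
    sims <- sort(sims, decreasing = TRUE)
    out[[q]] <- data.frame(query_id = q, model_id = names(sims),
                           tanimoto = unname(sims), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE))) else
    data.frame(query_id = character(0), model_id = character(0),
               tanimoto = numeric(0), stringsAsFactors = FALSE)
}

#' Read a spectral/standard availability index
#'
#' @param path TSV with columns \code{inchikey}, \code{method} (one of
#'   LC-MS, GC-MS, CE-MS, NMR, in-silico, other), \code{source}.
#' @return data.frame.
#' @export
readSpectralIndex <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "")
  need <- c("inchikey", "method")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("spectral index schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  vocab <- c("LC-MS", "GC-MS", "CE-MS", "NMR", "in-silico", "other")
  bad <- setdiff(unique(df$method), vocab)
  if (length(bad))
    stop("spectral index method(s) outside vocabulary: ",
         paste(bad, collapse = ", "))
  if (!"source" %in% names(df)) df$source <- NA_character_
  df
}

#' Spectral availability lookup
#'
#' Per record, one boolean column per method class. Matching is on the
#' full InChIKey first; records whose connectivity block (but not full
#' key) is indexed get the match with \code{block_fallback = TRUE}.
#'
#' @param records structure-record data.frame.
#' @param index data.frame from [readSpectralIndex()].
#' @return data.frame: id, inchikey, one logical column per method class,
#'   block_fallback.
#' @export
lookupIndex <- function(records, index) {
  vocab <- c("LC-MS", "GC-MS", "CE-MS", "NMR", "in-silico", "other")
  out <- data.frame(id = records$id, inchikey = records$inchikey,
                    stringsAsFactors = FALSE)
  for (v in vocab) out[[v]] <- FALSE
  out$block_fallback <- FALSE
  idxBlock <- inchikeyBlock1(index$inchikey)
  for (i in seq_len(nrow(records))) {
    key <- records$inchikey[i]
    if (is.na(key)) next
    full <- index$method[index$inchikey == key]
    if (length(full)) {
      out[i, unique(full)] <- TRUE
    } else {
      blk <- index$method[idxBlock == inchikeyBlock1(key)]
      if (length(blk)) {
        out[i, unique(blk)] <- TRUE
        out$block_fallback[i] <- TRUE
      }
    }
  }
  out
}
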