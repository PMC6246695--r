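#' Seeded toy-network generator
#'
#' Emits a linear uptake-to-biomass chain whose maximum throughput is
#' planted by a single bottleneck bound, plus dead-end reactions that can
#' never carry flux. The planted truth (optimum, blocked set) is what the
#' flux-analysis operations must recover exactly.
#'
#' @param seed integer seed; generators are pure functions of their seed
#'   and parameters.
#' @param n_chain chain length (internal metabolites), >= 2.
#' @param n_blocked number of planted dead-end reactions.
#' @param bottleneck the planted optimum (one chain bound set to it).
#' @return list(model, truth): truth has \code{optimum}, \code{blocked},
#'   \code{objective}, and generator metadata.
#' @export
makeToyNetwork <- function(seed, n_chain = 6, n_blocked = 2,
                           bottleneck = 10) {
  stopifnot(n_chain >= 2, bottleneck > 0, n_blocked >= 0)
  rng <- seededRNG(seed, "toy")
  m <- newModel(sprintf("toy_s%d", seed), c(c = "cytosol", e = "extracellular"))
  mets <- sprintf("met%d_c", seq_len(n_chain))
  for (id in mets) m <- addMetabolite(m, id)
  m <- addReaction(m, "EX_up", stats::setNames(1, mets[1]), lb = 0,
                   ub = 1000, is_exchange = TRUE)
  bpos <- 1L + (rng(1L) %% n_chain)  # which chain step carries the bottleneck
  for (i in seq_len(n_chain - 1L)) {
    ub <- if (i == bpos) bottleneck else 1000
    m <- addReaction(m, sprintf("CH%d", i),
                     stats::setNames(c(-1, 1), c(mets[i], mets[i + 1L])),
                     lb = 0, ub = ub)
  }
  bmUb <- if (bpos == n_chain) bottleneck else 1000
  m <- addReaction(m, "BIOMASS", stats::setNames(-1, mets[n_chain]),
                   lb = 0, ub = bmUb, is_biomass = TRUE, is_exchange = FALSE)
  blocked <- character(0)
  for (k in seq_len(n_blocked)) {
    a <- sprintf("dead%da_c", k); b <- sprintf("dead%db_c", k)
    m <- addMetabolite(m, a); m <- addMetabolite(m, b)
    rid <- sprintf("DEAD%d", k)
    m <- addReaction(m, rid, stats::setNames(c(-1, 1), c(a, b)), lb = 0)
    blocked <- c(blocked, rid)
  }
  m@objective <- "BIOMASS"
  list(model = m,
       truth = list(optimum = bottleneck, blocked = sort(blocked),
                    objective = "BIOMASS",
                    generator = list(name = "makeToyNetwork", version = 1L,
                                     seed = seed)))
}

# deterministic integer stream: distinct streams per generator label
seededRNG <- function(seed, label) {
  off <- sum(utf8ToInt(label))
  state <- (as.integer(seed) + off) %% 2147483647L
  if (state <= 0L) state <- state + 2147483646L
  function(n) {
    out <- integer(n)
    for (i in seq_len(n)) {
      state <<- as.integer((as.double(state) * 16807) %% 2147483647)
      out[i] <- state
    }
    out
  }
}

#' Seeded duplicate-planted model pair
#'
#' Builds two overlapping models: model 2 shares planted reactions with
#' model 1 as \code{n_exact} verbatim copies, \code{n_proton} copies
#' carrying one extra cytosolic proton (so only model 1's version is
#' elementally balanced), and \code{n_gpr} exact-stoichiometry copies with
#' a different gene rule. All other reactions are unique to their model
#' (disjoint metabolite pools, so no accidental signature collisions).
#' Metabolites carry randomly generated formulas with products summing the
#' substrates, making every planted model-1 reaction balanced.
#'
#' @param seed integer seed.
#' @param n_core reactions in model 1; must cover the planted counts.
#' @param n_exact,n_proton,n_gpr planted duplicate counts by mode.
#' @return list(model1, model2, truth); truth$pairs has columns
#'   \code{id1}, \code{id2}, \code{mode} (exact/proton/gpr-variant).
#' @export
makeDuplicatePair <- function(seed, n_core = 8, n_exact = 2, n_proton = 2,
                              n_gpr = 1) {
  stopifnot(n_exact >= 0, n_proton >= 0, n_gpr >= 0,
            n_core >= n_exact + n_proton + n_gpr)
  rng <- seededRNG(seed, "pair")
  m1 <- newModel("m1", c(c = "cytosol"))
  m2 <- newModel("m2", c(c = "cytosol"))
  proton <- "h_c"
  m1 <- addMetabolite(m1, proton, name = "proton", formula = "H", charge = 1)
  m2 <- addMetabolite(m2, proton, name = "proton", formula = "H", charge = 1)
  randFormula <- function() {
    c0 <- 1L + rng(1L) %% 12L; h <- 1L + rng(1L) %% 20L; o <- rng(1L) %% 8L
    formatFormula(stats::setNames(as.integer(c(c0, h, o)),
                                  c("C", "H", "O"))[c(c0, h, o) > 0])
  }
  genePool <- sprintf("WBGene%08d", 1:40)
  variantPool <- sprintf("WBGene%08d", 41:60)  # reserved: variant rules truly differ
  mkRule <- function() {
    k <- 1L + rng(1L) %% 2L
    paste(genePool[1L + rng(k) %% 40L], collapse = " or ")
  }
  # planted shared reactions live on a shared metabolite pool "s<i>"
  truth <- list()
  nShared <- n_exact + n_proton + n_gpr
  sharedRxn <- function(i) {
    subF <- c(randFormula(), randFormula())
    prodF <- formulaCombine(subF, c(1, 1))
    ids <- sprintf("s%d_%d_c", i, 1:3)
    list(mets = data.frame(id = ids, formula = c(subF, prodF),
                           stringsAsFactors = FALSE),
         stoich = stats::setNames(c(-1, -1, 1), ids))
  }
  for (i in seq_len(nShared)) {
    rx <- sharedRxn(i)
    mode <- if (i <= n_exact) "exact"
      else if (i <= n_exact + n_proton) "proton" else "gpr-variant"
    rule <- mkRule()
    for (k in seq_len(nrow(rx$mets))) {
      m1 <- addMetabolite(m1, rx$mets$id[k], formula = rx$mets$formula[k],
                          charge = 0)
      m2 <- addMetabolite(m2, rx$mets$id[k], formula = rx$mets$formula[k],
                          charge = 0)
    }
    id1 <- sprintf("R1_%d", i); id2 <- sprintf("R2_%d", i)
    m1 <- addReaction(m1, id1, rx$stoich, lb = 0, gene_rule = rule)
    st2 <- rx$stoich
    rule2 <- rule
    if (mode == "proton") st2 <- c(st2, stats::setNames(1, proton))
    if (mode == "gpr-variant")
      rule2 <- paste(rule, "or", variantPool[1L + rng(1L) %% 20L])
    m2 <- addReaction(m2, id2, st2, lb = 0, gene_rule = rule2)
    truth[[i]] <- data.frame(id1 = id1, id2 = id2, mode = mode,
                             stringsAsFactors = FALSE)
  }
  # unique filler reactions on disjoint pools
  uniqueRxn <- function(model, tag, i) {
    ids <- sprintf("%s%d_%d_c", tag, i, 1:2)
    f <- randFormula()
    model <- addMetabolite(model, ids[1], formula = f, charge = 0)
    model <- addMetabolite(model, ids[2], formula = f, charge = 0)
    addReaction(model, sprintf("R%s_%d", toupper(tag), i),
                stats::setNames(c(-1, 1), ids), lb = 0, gene_rule = mkRule())
  }
  for (i in seq_len(n_core - nShared)) m1 <- uniqueRxn(m1, "u", i)
  for (i in seq_len(max(0L, n_core - nShared))) m2 <- uniqueRxn(m2, "v", i)
  pairs <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id1 = character(0), id2 = character(0), mode = character(0))
  list(model1 = m1, model2 = m2,
       truth = list(pairs = pairs,
                    generator = list(name = "makeDuplicatePair", version = 1L,
                                     seed = seed)))
}

#' Seeded structure-panel generator
#'
#' Draws chemically valid structures from homologous-series SMILES
#' vocabularies (alkyl alcohols, fatty acids, diols and amines) and plants
#' a controlled entity overlap between a "model" panel and a "detected"
#' panel: \code{round(overlap_fraction * n_detected)} detected records
#' share connectivity blocks with model records, the rest are drawn from
#' series reserved for the detected side. Adjacent homologs in a series
#' are more similar than distant ones, which the Tanimoto operations must
#' reproduce.
#'
#' @param seed integer seed.
#' @param n_model,n_detected panel sizes.
#' @param overlap_fraction fraction of detected records whose entity is
#'   also in the model panel (0..1).
#' @return list(modelRecords, detectedRecords, truth); truth records the
#'   planted partition counts.
#' @export
makeStructurePanel <- function(seed, n_model = 12, n_detected = 10,
                               overlap_fraction = 0.5) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  rng <- seededRNG(seed, "panel")
  chain <- function(n) paste(rep("C", n), collapse = "")
  series <- list(
    alcohol = function(n) paste0(chain(n + 1), "O"),
    acid    = function(n) paste0(chain(n), "C(=O)O"),
    diol    = function(n) paste0("OC", chain(n), "O"),
    amine   = function(n) paste0(chain(n + 1), "N"))
  mkSmiles <- function(fams, k) {
    out <- character(0); n <- 1L
    while (length(out) < k) {
      for (f in fams) {
        out <- c(out, series[[f]](n))
        if (length(out) >= k) break
      }
      n <- n + 1L
    }
    out[seq_len(k)]
  }
  nOverlap <- round(overlap_fraction * n_detected)
  if (nOverlap > n_model)
    stop("overlap larger than the model panel; increase n_model")
  modelSmiles <- mkSmiles(c("alcohol", "acid"), n_model)
  ovIdx <- sort(1L + (rng(n_model)[seq_len(nOverlap)] %% n_model))
  while (anyDuplicated(ovIdx)) {  # resample collisions deterministically
    dup <- which(duplicated(ovIdx))
    ovIdx[dup] <- 1L + (rng(length(dup)) %% n_model)
    ovIdx <- sort(ovIdx)
  }
  detSmiles <- c(modelSmiles[ovIdx],
                 mkSmiles(c("diol", "amine"), n_detected - nOverlap))
  rec <- function(prefix, smiles) {
    df <- data.frame(id = sprintf("%s%02d", prefix, seq_along(smiles)),
                     name = smiles, inchi = NA_character_,
                     inchikey = NA_character_, smiles = smiles,
                     formula = NA_character_, charge = 0,
                     source = if (prefix == "mod") "model" else "literature",
                     detection_count = NA_integer_,
                     stringsAsFactors = FALSE)
    deriveInchikeys(df)
  }
  modelRecords <- rec("mod", modelSmiles)
  detectedRecords <- rec("det", detSmiles)
  mk <- unique(inchikeyBlock1(modelRecords$inchikey))
  dk <- unique(inchikeyBlock1(detectedRecords$inchikey))
  list(modelRecords = modelRecords, detectedRecords = detectedRecords,
       truth = list(n_overlap = length(intersect(mk, dk)),
                    n_model_entities = length(mk),
                    n_detected_entities = length(dk),
                    planted_overlap = nOverlap,
                    generator = list(name = "makeStructurePanel", version = 1L,
                                     seed = seed)))
}
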