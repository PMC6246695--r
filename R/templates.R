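# Charged-species reference formulas (cytosolic pH convention): the
# currency set shared by the pathway templates. CoA-containing species are
# built by group arithmetic from these so every emitted reaction balances
# by construction.
currencyFormulas <- function() {
  list(
    h2o    = list(f = "H2O",              c = 0),
    h      = list(f = "H",                c = 1),
    o2     = list(f = "O2",               c = 0),
    h2o2   = list(f = "H2O2",             c = 0),
    pi     = list(f = "HO4P",             c = -2),
    ppi    = list(f = "HO7P2",            c = -3),
    atp    = list(f = "C10H12N5O13P3",    c = -4),
    amp    = list(f = "C10H12N5O7P",      c = -2),
    nad    = list(f = "C21H26N7O14P2",    c = -1),
    nadh   = list(f = "C21H27N7O14P2",    c = -2),
    nadp   = list(f = "C21H25N7O17P3",    c = -3),
    nadph  = list(f = "C21H26N7O17P3",    c = -4),
    coa    = list(f = "C21H32N7O16P3S",   c = -4),
    accoa  = list(f = "C23H34N7O17P3S",   c = -4),
    glc__D = list(f = "C6H12O6",          c = 0),
    g1p    = list(f = "C6H11O9P",         c = -2),
    udpg   = list(f = "C15H22N2O17P2",    c = -2),
    udp    = list(f = "C9H11N2O12P2",     c = -3),
    tre    = list(f = "C12H22O11",        c = 0)
  )
}

fragmentHost <- function(id, compartments = c(c = "cytosol", e = "extracellular")) {
  newModel(id, compartments)
}

addCurrency <- function(model, which, compartment = "c") {
  ref <- currencyFormulas()
  for (w in which) {
    mid <- paste0(w, "_", compartment)
    if (!is.na(metaboliteRow(model, mid))) next
    model <- addMetabolite(model, mid, name = w, compartment = compartment,
                           formula = ref[[w]]$f, charge = ref[[w]]$c)
  }
  model
}

#' Phenomenological glycogen cycle
#'
#' Glycogen's stochastic branching makes a mechanistic model impossible,
#' so the cycle is phenomenological: it consumes the correct amount of
#' UDP-glucose on synthesis, forms the correct ratio of alpha(1,4) and
#' alpha(1,6) bonds, and returns the correct glucose-1-phosphate/glucose
#' ratio on breakdown, with exactly one debranching event per unit and no
#' maltose reactions. Six glycogen forms (primer and three elongation
#' ladders, the mature branched form, and the limit dextrin left when
#' phosphorylase stalls at the branch) connected by nine reactions: five
#' synthesis steps from glycogenin consuming 12 UDP-glucose in total, and
#' four breakdown steps releasing 11 glucose-1-phosphate plus 1 glucose
#' (residue conservation: 12 = 11 + 1). Glycogenin itself is carried as a
#' generic R-group species so every reaction is elementally balanced.
#'
#' @return a pathway fragment: list with \code{model} (a
#'   [GSModel-class]), \code{forms} (ids of the glycogen-form species),
#'   \code{synthesis}/\code{breakdown} (reaction ids), \code{net} (the
#'   declared net cycle stoichiometry for audit), \code{subsystem}.
#' @examples
#' frag <- glycogenModule()
#' nrow(reactions(frag$model))   # 9
#' length(frag$forms)            # 6
#' @export
glycogenModule <- function() {
  m <- fragmentHost("glycogen_module", c(c = "cytosol"))
  m <- addCurrency(m, c("udpg", "udp", "h", "pi", "g1p", "glc__D", "h2o"))
  res <- "C6H10O5"  # one glucosyl residue
  gin <- "glyg_c"
  m <- addMetabolite(m, gin, name = "glycogenin", compartment = "c",
                     formula = "R", charge = 0)
  forms <- c(glyg2 = 2L, glyg6 = 6L, glyg9 = 9L, glyg11 = 11L,
             glygB = 12L, glygLD = 7L)
  formNames <- c(glyg2 = "glycogen primer (2 residues)",
                 glyg6 = "glycogen chain (6 residues)",
                 glyg9 = "glycogen chain (9 residues)",
                 glyg11 = "glycogen chain (11 residues)",
                 glygB = "glycogen, branched (12 residues)",
                 glygLD = "limit dextrin (7 residues)")
  for (f in names(forms)) {
    m <- addMetabolite(m, paste0(f, "_c"), name = formNames[[f]],
                       compartment = "c",
                       formula = formulaCombine(c("R", res), c(1, forms[[f]])),
                       charge = 0)
  }
  syn <- list(  # from, to, n UDP-glucose
    GLYSYN1 = c("glyg",   "glyg2",  2),
    GLYSYN2 = c("glyg2",  "glyg6",  4),
    GLYSYN3 = c("glyg6",  "glyg9",  3),
    GLYSYN4 = c("glyg9",  "glyg11", 2),
    GLYSYN5 = c("glyg11", "glygB",  1))  # branching step: the alpha(1,6) bond
  synGene <- c(GLYSYN1 = "gsy-1", GLYSYN2 = "gsy-1", GLYSYN3 = "gsy-1",
               GLYSYN4 = "gsy-1", GLYSYN5 = "T04A8.7")
  for (rid in names(syn)) {
    p <- syn[[rid]]; n <- as.numeric(p[3])
    st <- stats::setNames(
      c(-1, -n, 1, n, n),
      c(paste0(p[1], "_c"), "udpg_c", paste0(p[2], "_c"), "udp_c", "h_c"))
    m <- addReaction(m, rid, st, lb = 0, ub = 1000, gene_rule = synGene[[rid]],
                     subsystem = "glycogen metabolism",
                     notes = list(phase = "synthesis"))
  }
  brk <- list(  # from, to, n phosphorolysis events (G1P released)
    GLYBRK1 = c("glygB",  "glygLD", 5),
    GLYBRK3 = c("glyg6",  "glyg2",  4),
    GLYBRK4 = c("glyg2",  "glyg",   2))
  for (rid in names(brk)) {
    p <- brk[[rid]]; n <- as.numeric(p[3])
    st <- stats::setNames(
      c(-1, -n, 1, n),
      c(paste0(p[1], "_c"), "pi_c", paste0(p[2], "_c"), "g1p_c"))
    m <- addReaction(m, rid, st, lb = 0, ub = 1000, gene_rule = "pyg-1",
                     subsystem = "glycogen metabolism",
                     notes = list(phase = "breakdown"))
  }
  # the single debranching (alpha(1,6)) event per unit: releases free glucose
  m <- addReaction(m, "GLYBRK2",
                   c(glygLD_c = -1, h2o_c = -1, glyg6_c = 1, glc__D_c = 1),
                   lb = 0, ub = 1000, gene_rule = "agl-1",
                   subsystem = "glycogen metabolism",
                   notes = list(phase = "breakdown"))
  ord <- c("GLYSYN1", "GLYSYN2", "GLYSYN3", "GLYSYN4", "GLYSYN5",
           "GLYBRK1", "GLYBRK2", "GLYBRK3", "GLYBRK4")
  m@reactions <- m@reactions[match(ord, m@reactions$id), , drop = FALSE]
  rownames(m@reactions) <- NULL
  list(model = m,
       forms = paste0(names(forms), "_c"),
       synthesis = names(syn),
       breakdown = c("GLYBRK1", "GLYBRK2", "GLYBRK3", "GLYBRK4"),
       net = c(udpg_c = -12, pi_c = -11, h2o_c = -1,
               udp_c = 12, h_c = 12, g1p_c = 11, glc__D_c = 1),
       subsystem = "glycogen metabolism")
}

# ascaroside side-chain bookkeeping: free ascaroside acid (neutral) of side
# chain length n is ascarylose + hydroxy fatty acid - H2O.
ascrFormula <- function(n) sprintf("C%dH%dO6", n + 6, 2 * n + 10)

#' Ascaroside biosynthesis via peroxisomal beta-oxidation
#'
#' Builds the chain-shortening pathway for simple ascarosides: a lump
#' reaction attaching ascarylose (from glucose) to an omega- or
#' omega-1-hydroxy fatty acid, activation of the long-chain ascaroside to
#' its CoA thioester (charge -4 convention), \code{(start-end)/2} rounds
#' of beta-oxidation — each round of four reactions carrying, in order,
#' the gene associations acox-1 (WBGene00008564), maoc-1 (WBGene00017123),
#' dhs-28 (WBGene00000991) and daf-22 (WBGene00013284), shortening the
#' side chain by two carbons and releasing acetyl-CoA — plus one CoA
#' hydrolysis per chain length to the free ascaroside and one export
#' reaction per free ascaroside to the extracellular space. The pathway is
#' placed in the cytosol with a peroxisome-like subsystem tag (the
#' four-compartment convention has no explicit peroxisome).
#'
#' @param side_chain_start,side_chain_end side-chain carbon counts;
#'   \code{start > end >= 3}, \code{start - end} even.
#' @param hydroxylation \code{"omega"} or \code{"omega-1"} (recorded in
#'   species naming only; the formula is the same positional isomer).
#' @return a pathway fragment (list with \code{model}, \code{rounds},
#'   \code{round_reactions}, \code{subsystem}).
#' @examples
#' frag <- ascarosidePathway(15, 5)
#' frag$rounds                       # 5
#' length(frag$round_reactions)      # 20
#' @export
ascarosidePathway <- function(side_chain_start, side_chain_end,
                              hydroxylation = c("omega", "omega-1")) {
  hydroxylation <- match.arg(hydroxylation)
  if (side_chain_end < 3)
    stop("side_chain_end must be >= 3 (shortest physiological side chain)")
  if (side_chain_start <= side_chain_end)
    stop("side_chain_start must exceed side_chain_end")
  if ((side_chain_start - side_chain_end) %% 2 != 0)
    stop("side_chain_start - side_chain_end must be even ",
         "(each beta-oxidation round removes two carbons)")
  m <- fragmentHost("ascaroside_module")
  m <- addCurrency(m, c("glc__D", "h2o", "h", "o2", "h2o2", "nad", "nadh",
                        "nadp", "nadph", "coa", "accoa", "atp", "amp", "ppi"))
  lens <- seq(side_chain_start, side_chain_end, by = -2)
  n0 <- side_chain_start
  # omega(-1)-hydroxy fatty acid, carboxylate form
  m <- addMetabolite(m, paste0("hfa", n0, "_c"),
    name = sprintf("%s-hydroxy C%d fatty acid", hydroxylation, n0),
    compartment = "c", formula = sprintf("C%dH%dO3", n0, 2 * n0 - 1),
    charge = -1)
  coaF <- currencyFormulas()$coa$f
  for (n in lens) {
    free <- ascrFormula(n)
    m <- addMetabolite(m, sprintf("ascr%d_c", n),
      name = sprintf("ascaroside C%d side chain", n), compartment = "c",
      formula = formulaCombine(c(free, "H"), c(1, -1)), charge = -1)
    m <- addMetabolite(m, sprintf("ascr%d_e", n),
      name = sprintf("ascaroside C%d side chain", n), compartment = "e",
      formula = formulaCombine(c(free, "H"), c(1, -1)), charge = -1)
    acyl <- formulaCombine(c(free, coaF, "H2O"), c(1, 1, -1))
    m <- addMetabolite(m, sprintf("ascrcoa%d_c", n),
      name = sprintf("ascaroside C%d CoA thioester", n), compartment = "c",
      formula = acyl, charge = -4)
    if (n > side_chain_end) {
      m <- addMetabolite(m, sprintf("ascrecoa%d_c", n),
        name = sprintf("2-enoyl ascaroside C%d CoA", n), compartment = "c",
        formula = formulaCombine(c(acyl, "H2"), c(1, -1)), charge = -4)
      m <- addMetabolite(m, sprintf("ascrhcoa%d_c", n),
        name = sprintf("3-hydroxy ascaroside C%d CoA", n), compartment = "c",
        formula = formulaCombine(c(acyl, "O"), c(1, 1)), charge = -4)
      m <- addMetabolite(m, sprintf("ascrocoa%d_c", n),
        name = sprintf("3-oxo ascaroside C%d CoA", n), compartment = "c",
        formula = formulaCombine(c(acyl, "O", "H2"), c(1, 1, -1)), charge = -4)
    }
  }
  sub <- "ascaroside biosynthesis (peroxisome-like)"
  # lump: ascarylose from glucose, attached to the hydroxy fatty acid;
  # the 3,6-dideoxygenation is charged to NADPH
  m <- addReaction(m, "ASCRLUMP", stats::setNames(
    c(-1, -1, -2, -2, 1, 3, 2),
    c("glc__D_c", paste0("hfa", n0, "_c"), "nadph_c", "h_c",
      sprintf("ascr%d_c", n0), "h2o_c", "nadp_c")),
    lb = 0, subsystem = sub)
  # activation to the CoA thioester
  m <- addReaction(m, sprintf("ASCRACT%d", n0), stats::setNames(
    c(-1, -1, -1, 1, 1, 1),
    c(sprintf("ascr%d_c", n0), "atp_c", "coa_c",
      sprintf("ascrcoa%d_c", n0), "amp_c", "ppi_c")),
    lb = 0, subsystem = sub)
  roundRxns <- character(0)
  for (n in lens[lens > side_chain_end]) {
    ids <- sprintf(c("ACOX%d", "MAOC%d", "DHS%d", "DAF22_%d"), n)
    m <- addReaction(m, ids[1], stats::setNames(
      c(-1, -1, 1, 1), c(sprintf("ascrcoa%d_c", n), "o2_c",
                         sprintf("ascrecoa%d_c", n), "h2o2_c")),
      lb = 0, gene_rule = "WBGene00008564", subsystem = sub)
    m <- addReaction(m, ids[2], stats::setNames(
      c(-1, -1, 1), c(sprintf("ascrecoa%d_c", n), "h2o_c",
                      sprintf("ascrhcoa%d_c", n))),
      lb = 0, gene_rule = "WBGene00017123", subsystem = sub)
    m <- addReaction(m, ids[3], stats::setNames(
      c(-1, -1, 1, 1, 1), c(sprintf("ascrhcoa%d_c", n), "nad_c",
                            sprintf("ascrocoa%d_c", n), "nadh_c", "h_c")),
      lb = 0, gene_rule = "WBGene00000991", subsystem = sub)
    m <- addReaction(m, ids[4], stats::setNames(
      c(-1, -1, 1, 1), c(sprintf("ascrocoa%d_c", n), "coa_c",
                         sprintf("ascrcoa%d_c", n - 2), "accoa_c")),
      lb = 0, gene_rule = "WBGene00013284", subsystem = sub)
    roundRxns <- c(roundRxns, ids)
  }
  for (n in lens) {
    m <- addReaction(m, sprintf("ASCRHYD%d", n), stats::setNames(
      c(-1, -1, 1, 1, 1),
      c(sprintf("ascrcoa%d_c", n), "h2o_c", sprintf("ascr%d_c", n),
        "coa_c", "h_c")),
      lb = 0, subsystem = sub)
    m <- addReaction(m, sprintf("ASCRTEX%d", n), stats::setNames(
      c(-1, 1), c(sprintf("ascr%d_c", n), sprintf("ascr%d_e", n))),
      lb = 0, is_exchange = FALSE, subsystem = sub)
  }
  list(model = m,
       rounds = as.integer((side_chain_start - side_chain_end) / 2),
       round_reactions = roundRxns,
       chain_lengths = lens, subsystem = sub)
}

#' Maradolipid biosynthesis by stepwise trehalose acylation
#'
#' Maradolipids are the 6,6'-diacyltrehalose lipids of dauer larvae; the
#' lyso form carries one acyl chain. For each fatty-acyl pair the module
#' emits two acylation reactions using fatty-acyl-CoAs as donors:
#' trehalose + acyl-CoA -> lysomaradolipid + CoA, then
#' lysomaradolipid + acyl-CoA' -> maradolipid + CoA.
#'
#' @param fatty_acid_pairs list of 2-element integer vectors: the two acyl
#'   chain carbon counts per maradolipid species.
#' @return a pathway fragment (list with \code{model}, \code{species},
#'   \code{subsystem}).
#' @examples
#' frag <- maradolipidModule(list(c(15, 15)))
#' nrow(reactions(frag$model))   # 2
#' @export
maradolipidModule <- function(fatty_acid_pairs) {
  if (length(fatty_acid_pairs) == 0L)
    stop("at least one fatty-acyl pair is required")
  m <- fragmentHost("maradolipid_module", c(c = "cytosol"))
  m <- addCurrency(m, c("tre", "coa"))
  coaF <- currencyFormulas()$coa$f
  treF <- currencyFormulas()$tre$f
  faF <- function(n) sprintf("C%dH%dO2", n, 2 * n)
  sub <- "maradolipid biosynthesis"
  species <- character(0)
  for (p in fatty_acid_pairs) {
    stopifnot(length(p) == 2L, all(p >= 2))
    n1 <- p[1]; n2 <- p[2]
    for (n in unique(c(n1, n2))) {
      fid <- sprintf("facoa%d_c", n)
      if (is.na(metaboliteRow(m, fid)))
        m <- addMetabolite(m, fid, name = sprintf("C%d fatty acyl-CoA", n),
          compartment = "c",
          formula = formulaCombine(c(faF(n), coaF, "H2O"), c(1, 1, -1)),
          charge = -4)
    }
    lysoId <- sprintf("lysomara%d_c", n1)
    if (is.na(metaboliteRow(m, lysoId)))
      m <- addMetabolite(m, lysoId,
        name = sprintf("lysomaradolipid (C%d)", n1), compartment = "c",
        formula = formulaCombine(c(treF, faF(n1), "H2O"), c(1, 1, -1)),
        charge = 0)
    maraId <- sprintf("mara%d_%d_c", n1, n2)
    m <- addMetabolite(m, maraId,
      name = sprintf("maradolipid (C%d/C%d)", n1, n2), compartment = "c",
      formula = formulaCombine(c(treF, faF(n1), faF(n2), "H2O"), c(1, 1, 1, -2)),
      charge = 0)
    r1 <- sprintf("MARA1_%d", n1)
    if (is.na(reactionRow(m, r1)))
      m <- addReaction(m, r1, stats::setNames(
        c(-1, -1, 1, 1),
        c("tre_c", sprintf("facoa%d_c", n1), lysoId, "coa_c")),
        lb = 0, subsystem = sub)
    m <- addReaction(m, sprintf("MARA2_%d_%d", n1, n2), stats::setNames(
      c(-1, -1, 1, 1),
      c(lysoId, sprintf("facoa%d_c", n2), maraId, "coa_c")),
      lb = 0, subsystem = sub)
    species <- c(species, lysoId, maraId)
  }
  list(model = m, species = unique(species), subsystem = sub)
}
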