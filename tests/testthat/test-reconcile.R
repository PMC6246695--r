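mappingFixture <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  header <- "namespace\tsource_id\ttarget_id\txrefs\tcharge\tformula"
  writeLines(c(header, rows), f)
  f
}

test_that("gene mapping rewrites gene sets and rules, reports unmapped", {
  tab <- readMappingTable(mappingFixture(c(
    "common\tacox-1\tWBGene00008564\t\t\t",
    "common\tmaoc-1\tWBGene00017123\t\t\t")))
  m <- newModel("g", c(c = "cytosol"))
  m <- addMetabolite(m, "x_c"); m <- addMetabolite(m, "y_c")
  m <- addReaction(m, "R1", c(x_c = -1, y_c = 1), lb = 0,
                   gene_rule = "acox-1 or keep-me")
  res <- mapGeneIds(m, tab)
  expect_true("WBGene00008564" %in% genes(res$model))
  expect_false("acox-1" %in% genes(res$model))
  expect_identical(res$report$unmapped, "keep-me")
  expect_true(gprEqual(reactions(res$model)$gene_rule[1],
                       "WBGene00008564 or keep-me"))
  # idempotence: second application is identity
  res2 <- mapGeneIds(res$model, tab)
  expect_identical(genes(res2$model), genes(res$model))
  expect_identical(reactions(res2$model)$gene_rule,
                   reactions(res$model)$gene_rule)
})

test_that("aliases collapsing to one target reduce the unique-gene count", {
  tab <- readMappingTable(mappingFixture(c(
    "common\tgeneA\tWBGene00000001\t\t\t",
    "common\tgeneB\tWBGene00000001\t\t\t")))
  m <- newModel("g", c(c = "cytosol"))
  m <- addMetabolite(m, "x_c"); m <- addMetabolite(m, "y_c")
  m <- addReaction(m, "R1", c(x_c = -1, y_c = 1), lb = 0,
                   gene_rule = "geneA or geneB")
  res <- mapGeneIds(m, tab)
  expect_identical(res$report$nCollapsed, 1L)
  expect_identical(genes(res$model), "WBGene00000001")
  expect_identical(gprCanonicalize(reactions(res$model)$gene_rule[1]),
                   list("WBGene00000001"))
})

test_that("metabolite normalization renames with suffix kept and flags collisions", {
  tab <- readMappingTable(mappingFixture(c(
    "kegg\tC00031\tglc__D\tchebi:CHEBI:17634\t0\tC6H12O6",
    "kegg\tC00002\tatp\t\t-4\tC10H12N5O13P3",
    "kegg\tC99998\tclash\t\t\t",
    "kegg\tC99999\tclash\t\t\t")))
  m <- newModel("n", c(c = "cytosol"))
  m <- addMetabolite(m, "C00031_c"); m <- addMetabolite(m, "keepme_c")
  m <- addMetabolite(m, "C99998_c"); m <- addMetabolite(m, "C99999_c")
  m <- addReaction(m, "R1", c(C00031_c = -1, keepme_c = 1), lb = 0)
  res <- normalizeMetaboliteIds(m, tab)
  met <- metabolites(res$model)
  expect_true("glc__D_c" %in% met$id)
  expect_identical(met$formula[met$id == "glc__D_c"], "C6H12O6")
  expect_identical(met$annotations[[which(met$id == "glc__D_c")]]$chebi,
                   "CHEBI:17634")
  expect_identical(names(reactions(res$model)$stoich[[1]]),
                   c("glc__D_c", "keepme_c"))
  expect_true("keepme_c" %in% res$report$unmapped)
  # collision: both kept under source ids, flagged, not merged
  expect_identical(sort(res$report$collisions$source_id),
                   c("C99998_c", "C99999_c"))
  expect_true(all(c("C99998_c", "C99999_c") %in% met$id))
  # idempotence
  res2 <- normalizeMetaboliteIds(res$model, tab)
  expect_identical(metabolites(res2$model)$id, met$id)
})

test_that("duplicate metabolites merge per compartment with stoichiometry rewired", {
  m <- newModel("d", c(c = "cytosol", m = "mitochondrion"))
  m <- addMetabolite(m, "glu__L_c", annotations = list(chebi = "CHEBI:18237"))
  m <- addMetabolite(m, "glut_c", annotations = list(chebi = "CHEBI:18237"))
  m <- addMetabolite(m, "glu__L_m", annotations = list(chebi = "CHEBI:18237"))
  m <- addMetabolite(m, "akg_c")
  m <- addReaction(m, "R1", c(glut_c = -1, akg_c = 1), lb = 0)
  m <- addReaction(m, "T1", c(glu__L_c = -1, glu__L_m = 1), lb = 0)
  res <- deduplicateMetabolites(m, key = "chebi")
  met <- metabolites(res$model)
  # survivor is the lexicographically smallest id, same compartment only
  expect_true("glu__L_c" %in% met$id)
  expect_false("glut_c" %in% met$id)
  expect_true("glu__L_m" %in% met$id)
  expect_setequal(names(reactions(res$model)$stoich[[1]]),
                  c("glu__L_c", "akg_c"))
  expect_identical(res$report$merged$removed, "glut_c")
  expect_identical(nrow(validateModel(res$model)), 0L)
})

test_that("merging duplicates occurring in one reaction sums coefficients", {
  m <- newModel("z", c(c = "cytosol"))
  m <- addMetabolite(m, "a1_c", annotations = list(chebi = "CHEBI:1"))
  m <- addMetabolite(m, "a2_c", annotations = list(chebi = "CHEBI:1"))
  m <- addMetabolite(m, "b_c")
  # a1 consumed, a2 produced with equal coefficient: zero net, logged
  m <- addReaction(m, "R1", c(a1_c = -1, a2_c = 1, b_c = 1), lb = 0)
  res <- deduplicateMetabolites(m, key = "chebi")
  s <- reactions(res$model)$stoich[[1]]
  expect_identical(names(s), "b_c")
  expect_identical(res$report$zeroed$metabolite, "a1_c")
})

test_that("no shared keys leaves the model unchanged", {
  m <- chainModel()
  res <- deduplicateMetabolites(m, key = "auto")
  expect_identical(metabolites(res$model)$id, metabolites(m)$id)
  expect_identical(nrow(res$report$merged), 0L)
})

test_that("balance checking matches hand-summed formulas", {
  # textbook identity
  expect_true(checkBalance("WATER", waterModel())@balanced)
  # hexokinase with the proton left off the product side:
  # imbalance H:-1, charge -1
  m <- newModel("hk", c(c = "cytosol"))
  m <- addMetabolite(m, "glc_c", formula = "C6H12O6", charge = 0)
  m <- addMetabolite(m, "atp_c", formula = "C10H12N5O13P3", charge = -4)
  m <- addMetabolite(m, "g6p_c", formula = "C6H11O9P", charge = -2)
  m <- addMetabolite(m, "adp_c", formula = "C10H12N5O10P2", charge = -3)
  m <- addReaction(m, "HEX", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
                   lb = 0)
  b <- checkBalance("HEX", m)
  expect_true(b@determined)
  expect_false(b@balanced)
  expect_equal(b@elementImbalance, c(H = -1))
  expect_equal(b@chargeImbalance, -1)
  # generic group on one side only is flagged
  m2 <- newModel("r", c(c = "cytosol"))
  m2 <- addMetabolite(m2, "acoa_c", formula = "C2H4OR", charge = 0)
  m2 <- addMetabolite(m2, "ac_c", formula = "C2H4O", charge = 0)
  m2 <- addReaction(m2, "RX", c(acoa_c = -1, ac_c = 1), lb = 0)
  b2 <- checkBalance("RX", m2)
  expect_equal(b2@elementImbalance, c(R = -1))
  # missing formula: undetermined, never balanced
  m3 <- chainModel()
  b3 <- checkBalance("R_AB", m3)
  expect_false(b3@determined)
  expect_false(b3@balanced)
})

test_that("reversing a reaction negates all imbalances", {
  m <- newModel("hk", c(c = "cytosol"))
  m <- addMetabolite(m, "glc_c", formula = "C6H12O6", charge = 0)
  m <- addMetabolite(m, "atp_c", formula = "C10H12N5O13P3", charge = -4)
  m <- addMetabolite(m, "g6p_c", formula = "C6H11O9P", charge = -2)
  m <- addMetabolite(m, "adp_c", formula = "C10H12N5O10P2", charge = -3)
  m <- addReaction(m, "FWD", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
                   lb = 0)
  m <- addReaction(m, "REV", c(glc_c = 1, atp_c = 1, g6p_c = -1, adp_c = -1),
                   lb = 0)
  bf <- checkBalance("FWD", m); br <- checkBalance("REV", m)
  expect_equal(bf@elementImbalance, -br@elementImbalance)
  expect_equal(bf@chargeImbalance, -br@chargeImbalance)
})

test_that("metabolite dedup does not change balance status of formula-complete reactions", {
  m <- newModel("p", c(c = "cytosol"))
  m <- addMetabolite(m, "x1_c", formula = "C2H6O", charge = 0,
                     annotations = list(chebi = "CHEBI:9"))
  m <- addMetabolite(m, "x2_c", formula = "C2H6O", charge = 0,
                     annotations = list(chebi = "CHEBI:9"))
  m <- addMetabolite(m, "y_c", formula = "C2H6O", charge = 0)
  m <- addReaction(m, "R1", c(x1_c = -1, y_c = 1), lb = 0)
  m <- addReaction(m, "R2", c(x2_c = -1, y_c = 1), lb = 0)
  before <- vapply(reactions(m)$id, function(r) checkBalance(r, m)@balanced, TRUE)
  res <- deduplicateMetabolites(m, key = "chebi")
  after <- vapply(reactions(res$model)$id,
                  function(r) checkBalance(r, res$model)@balanced, TRUE)
  expect_identical(unname(before), unname(after))
})
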