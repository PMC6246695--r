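test_that("concatenation unions metabolites, genes and keeps all reactions", {
  d <- makeDuplicatePair(seed = 3, n_core = 6, n_exact = 1, n_proton = 1,
                         n_gpr = 1)
  cc <- concatModels(d$model1, d$model2)
  expect_identical(cc$report@nReactionsUnion,
                   nrow(reactions(d$model1)) + nrow(reactions(d$model2)))
  expect_identical(nrow(metabolites(cc$model)),
                   length(union(metabolites(d$model1)$id,
                                metabolites(d$model2)$id)))
  expect_identical(genes(cc$model),
                   sort(union(genes(d$model1), genes(d$model2))))
  # disjoint toy models: plain disjoint union
  a <- newModel("a", c(c = "cytosol"))
  a <- addMetabolite(a, "p_c"); a <- addMetabolite(a, "q_c")
  a <- addMetabolite(a, "r_c")
  a <- addReaction(a, "A1", c(p_c = -1, q_c = 1), lb = 0)
  a <- addReaction(a, "A2", c(q_c = -1, r_c = 1), lb = 0)
  b <- newModel("b", c(c = "cytosol"))
  b <- addMetabolite(b, "s_c"); b <- addMetabolite(b, "t_c")
  b <- addReaction(b, "B1", c(s_c = -1, t_c = 1), lb = 0)
  cc2 <- concatModels(a, b)
  expect_identical(nrow(metabolites(cc2$model)), 5L)
  expect_identical(nrow(reactions(cc2$model)), 3L)
})

test_that("reaction id clash keeps both copies with the second suffixed", {
  a <- newModel("a", c(c = "cytosol"))
  a <- addMetabolite(a, "p_c"); a <- addMetabolite(a, "q_c")
  a <- addReaction(a, "R1", c(p_c = -1, q_c = 1), lb = 0)
  b <- newModel("b", c(c = "cytosol"))
  b <- addMetabolite(b, "p_c"); b <- addMetabolite(b, "q_c")
  b <- addReaction(b, "R1", c(p_c = -2, q_c = 1), lb = 0)
  expect_warning(cc <- concatModels(a, b), "clash")
  expect_setequal(reactions(cc$model)$id, c("R1", "R1_b"))
})

test_that("signatures are orientation-symmetric for reversible reactions only", {
  m <- newModel("s", c(c = "cytosol"))
  for (id in c("a_c", "b_c", "x_c")) m <- addMetabolite(m, id)
  m <- addReaction(m, "F", c(a_c = -1, b_c = -1, x_c = 1), reversible = TRUE)
  m <- addReaction(m, "B", c(a_c = 1, b_c = 1, x_c = -1), reversible = TRUE)
  m <- addReaction(m, "Fi", c(a_c = -1, x_c = 1), lb = 0)
  m <- addReaction(m, "Bi", c(a_c = 1, x_c = -1), lb = 0)
  cfg <- mergeConfig()
  expect_identical(canonicalSignature("F", m, cfg)$string,
                   canonicalSignature("B", m, cfg)$string)
  expect_false(canonicalSignature("Fi", m, cfg)$string ==
                 canonicalSignature("Bi", m, cfg)$string)
})

test_that("signatures distinguish scaling and compartments", {
  m <- newModel("s", c(c = "cytosol", m = "mitochondrion"))
  for (id in c("a_c", "b_c", "a_m", "b_m")) m <- addMetabolite(m, id)
  m <- addReaction(m, "S1", c(a_c = -1, b_c = 1), lb = 0)
  m <- addReaction(m, "S2", c(a_c = -2, b_c = 2), lb = 0)
  m <- addReaction(m, "S3", c(a_m = -1, b_m = 1), lb = 0)
  cfg <- mergeConfig()
  sigs <- vapply(c("S1", "S2", "S3"),
                 function(r) canonicalSignature(r, m, cfg)$string, "")
  expect_identical(length(unique(sigs)), 3L)
})

test_that("proton stripping removes configured protons and flags the signature", {
  m <- newModel("s", c(c = "cytosol"))
  for (id in c("a_c", "b_c", "h_c")) m <- addMetabolite(m, id)
  m <- addReaction(m, "P1", c(h_c = -1, a_c = -1, b_c = 1), lb = 0)
  m <- addReaction(m, "P2", c(a_c = -1, b_c = 1), lb = 0)
  cfg <- mergeConfig()
  s1 <- stripProtons(canonicalSignature("P1", m, cfg), cfg)
  s2 <- stripProtons(canonicalSignature("P2", m, cfg), cfg)
  expect_true(s1$proton_stripped)
  expect_identical(s1$string, s2$string)
  expect_false("h" %in% s1$entries$key)
  # a signature without protons is unchanged except the flag
  s3 <- canonicalSignature("P2", m, cfg)
  expect_identical(stripProtons(s3, cfg)$entries, s3$entries)
})

test_that("planted duplicates are recovered exactly with correct modes", {
  d <- makeDuplicatePair(seed = 1, n_core = 8, n_exact = 3, n_proton = 2,
                         n_gpr = 1)
  cc <- concatModels(d$model1, d$model2)
  res <- deduplicateReactions(cc$model, primary_source = "m1")
  rp <- res$report@removedPairs
  expect_identical(nrow(rp), 6L)
  recovered <- ifelse(rp$match_mode == "proton", "proton",
                      ifelse(rp$gpr_merged, "gpr-variant", "exact"))
  truth <- d$truth$pairs
  expect_identical(rp$removed_id[order(rp$removed_id)],
                   truth$id2[order(truth$id2)])
  expect_identical(recovered[order(rp$removed_id)],
                   truth$mode[order(truth$id2)])
  expect_identical(rp$kept_id[order(rp$removed_id)],
                   truth$id1[order(truth$id2)])
  # conservation: final count = union - removed
  expect_identical(nrow(reactions(res$model)),
                   res$report@nReactionsUnion - res$report@nDuplicatesRemoved)
  # idempotence: rerunning removes nothing
  res2 <- deduplicateReactions(res$model, primary_source = "m1")
  expect_identical(res2$report@nDuplicatesRemoved, 0L)
})

test_that("proton-variant arbitration keeps the balanced stoichiometry", {
  d <- makeDuplicatePair(seed = 11, n_core = 4, n_exact = 0, n_proton = 1,
                         n_gpr = 0)
  cc <- concatModels(d$model1, d$model2)
  res <- deduplicateReactions(cc$model, primary_source = "m1")
  rp <- res$report@removedPairs
  expect_identical(rp$match_mode, "proton")
  # model 1's version is the balanced one in this fixture
  expect_identical(rp$balance_winner, "first")
  kept <- reactions(res$model)
  s <- kept$stoich[[match(rp$kept_id, kept$id)]]
  expect_false("h_c" %in% names(s))
  expect_true(checkBalance(rp$kept_id, res$model)@balanced)
})

test_that("second model's balanced version replaces stoichiometry and meta", {
  m1 <- newModel("m1", c(c = "cytosol"))
  m2 <- newModel("m2", c(c = "cytosol"))
  for (mm in c("a", "b")) {
    m1 <- addMetabolite(m1, paste0(mm, "_c"), formula = "C2H6O", charge = 0)
    m2 <- addMetabolite(m2, paste0(mm, "_c"), formula = "C2H6O", charge = 0)
  }
  m1 <- addMetabolite(m1, "h_c", formula = "H", charge = 1)
  m2 <- addMetabolite(m2, "h_c", formula = "H", charge = 1)
  # first model's version carries a spurious proton (unbalanced)
  m1 <- addReaction(m1, "RA", c(a_c = -1, b_c = 1, h_c = 1), lb = 0,
                    subsystem = "wrong")
  m2 <- addReaction(m2, "RB", c(a_c = -1, b_c = 1), lb = 0,
                    subsystem = "right")
  cc <- concatModels(m1, m2)
  res <- deduplicateReactions(cc$model, primary_source = "m1")
  rp <- res$report@removedPairs
  expect_identical(rp$balance_winner, "second")
  expect_identical(res$report@nBalanceCorrected, 1L)
  kept <- reactions(res$model)
  i <- match("RA", kept$id)
  expect_false("h_c" %in% names(kept$stoich[[i]]))
  expect_identical(kept$subsystem[i], "right")
})

test_that("both versions unbalanced: kept and flagged for curation", {
  m1 <- newModel("m1", c(c = "cytosol"))
  m2 <- newModel("m2", c(c = "cytosol"))
  for (mm in c("a", "b")) {
    m1 <- addMetabolite(m1, paste0(mm, "_c"), formula = "C2H6O", charge = 0)
    m2 <- addMetabolite(m2, paste0(mm, "_c"), formula = "C2H6O", charge = 0)
  }
  m1 <- addMetabolite(m1, "h_c", formula = "H", charge = 1)
  m2 <- addMetabolite(m2, "h_c", formula = "H", charge = 1)
  m1 <- addReaction(m1, "RA", c(a_c = -1, b_c = 1, h_c = 1), lb = 0)
  m2 <- addReaction(m2, "RB", c(a_c = -1, b_c = 1, h_c = 2), lb = 0)
  cc <- concatModels(m1, m2)
  res <- deduplicateReactions(cc$model, primary_source = "m1")
  expect_identical(res$report@nDuplicatesRemoved, 0L)
  expect_identical(nrow(res$report@curationFlags), 1L)
  expect_setequal(reactions(res$model)$id, c("RA", "RB"))
})

test_that("biomass reactions are never removed as duplicates", {
  m1 <- newModel("m1", c(c = "cytosol"))
  m2 <- newModel("m2", c(c = "cytosol"))
  m1 <- addMetabolite(m1, "x_c"); m2 <- addMetabolite(m2, "x_c")
  m1 <- addReaction(m1, "BIO1", c(x_c = -1), lb = 0, is_biomass = TRUE,
                    is_exchange = FALSE)
  m2 <- addReaction(m2, "BIO2", c(x_c = -1), lb = 0, is_biomass = TRUE,
                    is_exchange = FALSE)
  cc <- concatModels(m1, m2)
  res <- deduplicateReactions(cc$model, primary_source = "m1")
  expect_setequal(reactions(res$model)$id, c("BIO1", "BIO2"))
})

test_that("dedup agrees with a brute-force all-pairs signature scan", {
  for (seed in c(5, 23, 99)) {
    d <- makeDuplicatePair(seed = seed, n_core = 10, n_exact = 3,
                           n_proton = 2, n_gpr = 2)
    cc <- concatModels(d$model1, d$model2)
    res <- deduplicateReactions(cc$model, primary_source = "m1")
    expect_identical(sort(res$report@removedPairs$removed_id),
                     bruteForceDuplicates(cc$model, "m1"))
  }
})

test_that("guarded merge reverts viability-breaking removals only", {
  # chain with a redundant pair for one step and a unique producer step
  m <- chainModel()
  m <- addReaction(m, "R_AB_dup", c(A_c = -1, B_c = 1), lb = 0, ub = 1000)
  m@objective <- "EX_out"
  res <- guardedMerge(m, data.frame(
    keep_id = c("R_AB", "EX_up"),
    drop_id = c("R_AB_dup", "R_AB"),  # second candidate breaks the chain
    stringsAsFactors = FALSE))
  expect_identical(res$report@revertedMerges$drop_id, "R_AB")
  expect_false("R_AB_dup" %in% reactions(res$model)$id)
  expect_true("R_AB" %in% reactions(res$model)$id)
  # objective never dropped below tolerance
  expect_gt(fba(res$model, "EX_out", mode = "free-growth")$objective, 1e-6)
  # empty candidate list leaves the model unchanged
  res2 <- guardedMerge(m, NULL)
  expect_identical(nrow(reactions(res2$model)), nrow(reactions(m)))
})

test_that("guarded merge aborts on an inviable starting model", {
  m <- chainModel()
  m@reactions$ub[m@reactions$id == "R_AB"] <- 0  # break the internal chain
  m@objective <- "EX_out"
  expect_error(guardedMerge(m, NULL), "not viable")
})
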