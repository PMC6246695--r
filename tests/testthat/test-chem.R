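test_that("InChIKey connectivity block extraction validates and collapses stereo", {
  expect_identical(inchikeyBlock1("NBSCHQHZLSJFNQ-FPRJBGLDSA-N"),
                   "NBSCHQHZLSJFNQ")
  # galactose-6P vs glucose-6P: stereoisomers share the connectivity block
  expect_identical(inchikeyBlock1("NBSCHQHZLSJFNQ-FPRJBGLDSA-N"),
                   inchikeyBlock1("NBSCHQHZLSJFNQ-VFUOTHLCSA-N"))
  expect_error(inchikeyBlock1("ABC"), "malformed")
})

test_that("fingerprints are deterministic and canonical over SMILES order", {
  recs <- data.frame(id = c("etoh1", "etoh2", "hexol"),
                     smiles = c("CCO", "OCC", "CCCCCCO"),
                     stringsAsFactors = FALSE)
  fp <- fingerprintStructures(recs)
  expect_identical(nrow(fp), 3L)
  expect_identical(ncol(fp), 1024L)
  expect_identical(fp["etoh1", ], fp["etoh2", ])
  expect_true(sum(fp["hexol", ]) >= 1)
  # repeated computation is identical
  expect_identical(fingerprintStructures(recs), fp)
  # unparseable/generic structures: error in single mode, skipped in batch
  bad <- data.frame(id = c("ok", "generic"), smiles = c("CCO", "CC(*)O"),
                    stringsAsFactors = FALSE)
  expect_error(fingerprintStructures(bad, batch = FALSE), "generic")
  fpb <- fingerprintStructures(bad, batch = TRUE)
  expect_identical(attr(fpb, "skipped"), "generic")
  expect_identical(rownames(fpb), "ok")
})

test_that("tanimoto implements the set formula with its edge cases", {
  a <- rep(FALSE, 8); a[c(1, 2, 3)] <- TRUE
  b <- rep(FALSE, 8); b[c(2, 3, 4)] <- TRUE
  expect_equal(tanimoto(a, b), 0.5)   # 2 shared / 4 in union
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, rep(FALSE, 8)), 0)
  expect_equal(tanimoto(rep(FALSE, 8), rep(FALSE, 8)), 0)
  expect_error(tanimoto(a, rep(TRUE, 4)), "length mismatch")
})

test_that("tanimoto is symmetric, reflexive and bounded on random bit sets", {
  set.seed(17)
  for (k in 1:25) {
    a <- stats::runif(64) < 0.3
    b <- stats::runif(64) < 0.3
    t1 <- tanimoto(a, b)
    expect_identical(t1, tanimoto(b, a))
    expect_gte(t1, 0); expect_lte(t1, 1)
    if (any(a)) expect_equal(tanimoto(a, a), 1)
  }
})

test_that("tanimoto agrees with an independent contingency-table computation", {
  recs <- data.frame(id = c("a", "b"), smiles = c("CCCO", "CCCCO"),
                     stringsAsFactors = FALSE)
  fp <- fingerprintStructures(recs)
  ours <- tanimoto(fp["a", ], fp["b", ])
  ct <- table(factor(fp["a", ], c(FALSE, TRUE)),
              factor(fp["b", ], c(FALSE, TRUE)))
  oracle <- ct["TRUE", "TRUE"] / (sum(ct) - ct["FALSE", "FALSE"])
  expect_equal(unname(ours), unname(oracle))
})

test_that("coverage partitions entities with the set identities", {
  mk <- function(keys) data.frame(
    id = paste0("s", seq_along(keys)),
    inchikey = keys, stringsAsFactors = FALSE)
  key <- function(b) sprintf("%s-UHFFFAOYSA-N",
                             vapply(b, function(x)
                               paste(rep(x, 14), collapse = ""), ""))
  modelRecs <- mk(key(c("A", "B", "C")))
  detRecs <- mk(key(c("B", "C", "D", "E")))
  cov <- coverage(modelRecs, detRecs)
  expect_identical(length(cov@overlap), 2L)
  expect_identical(length(cov@modelOnly), 1L)
  expect_identical(length(cov@detectedOnly), 2L)
  expect_identical(length(cov@overlap) + length(cov@detectedOnly),
                   cov@nDetectedEntities)
  expect_identical(length(cov@overlap) + length(cov@modelOnly),
                   cov@nModelEntities)
  # swap symmetry up to relabeling
  cov2 <- coverage(detRecs, modelRecs)
  expect_identical(cov2@overlap, cov@overlap)
  expect_identical(cov2@modelOnly, cov@detectedOnly)
  # stereoisomer pair collapses to one entity
  stereo <- mk(c("NBSCHQHZLSJFNQ-FPRJBGLDSA-N", "NBSCHQHZLSJFNQ-VFUOTHLCSA-N"))
  expect_identical(coverage(stereo, stereo)@nModelEntities, 1L)
  # records without keys counted separately
  nk <- mk(c(key("A"), NA))
  expect_identical(coverage(nk, nk)@nModelNoKey, 1L)
})

test_that("structure panels drive coverage to the planted overlap", {
  p <- makeStructurePanel(seed = 4, n_model = 12, n_detected = 10,
                          overlap_fraction = 0.5)
  cov <- coverage(p$modelRecords, p$detectedRecords)
  expect_identical(length(cov@overlap), 5L)
  expect_identical(cov@nModelEntities, 12L)
  expect_identical(cov@nDetectedEntities, 10L)
  p0 <- makeStructurePanel(seed = 4, n_model = 6, n_detected = 6,
                           overlap_fraction = 0)
  expect_identical(length(coverage(p0$modelRecords, p0$detectedRecords)@overlap), 0L)
})

test_that("adjacent homologs are more similar than distant ones", {
  recs <- data.frame(id = c("c4", "c5", "c12"),
                     smiles = c("CCCCO", "CCCCCO", "CCCCCCCCCCCCO"),
                     stringsAsFactors = FALSE)
  fp <- fingerprintStructures(recs)
  expect_gt(tanimoto(fp["c4", ], fp["c5", ]),
            tanimoto(fp["c4", ], fp["c12", ]))
})

test_that("cutoff calibration separates reaction pairs from background", {
  # homologous elongation chain: every reaction converts Cn -> Cn+1 alcohol
  m <- newModel("chain", c(c = "cytosol"))
  n <- 8
  smiles <- vapply(seq_len(n), function(k)
    paste0(paste(rep("C", k + 2), collapse = ""), "O"), "")
  recs <- data.frame(id = sprintf("alc%d", seq_len(n)), smiles = smiles,
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) m <- addMetabolite(m, sprintf("alc%d_c", i))
  for (i in seq_len(n - 1))
    m <- addReaction(m, sprintf("E%d", i),
                     stats::setNames(c(-1, 1),
                                     sprintf("alc%d_c", c(i, i + 1))), lb = 0)
  cal <- calibrateCutoff(m, recs)
  expect_identical(cal$cutoff, 0.4)
  expect_gt(stats::median(cal$foreground), stats::median(cal$background))
  # foreground stochastically dominates background
  qs <- seq(0.1, 0.9, by = 0.2)
  expect_true(all(stats::quantile(cal$foreground, qs) >=
                    stats::quantile(cal$background, qs) - 1e-9))
})

test_that("hub exclusion removes currency pairs from the foreground", {
  m <- newModel("hub", c(c = "cytosol"))
  for (id in c("atp_c", "adp_c", "alcA_c", "alcB_c")) m <- addMetabolite(m, id)
  m <- addReaction(m, "K1", c(alcA_c = -1, atp_c = -1, alcB_c = 1, adp_c = 1),
                   lb = 0)
  recs <- data.frame(id = c("atp", "adp", "alcA", "alcB"),
                     smiles = c("Nc1ncnc2n(cnc12)C1OC(COP(O)(=O)OP(O)(=O)OP(O)(O)=O)C(O)C1O",
                                "Nc1ncnc2n(cnc12)C1OC(COP(O)(=O)OP(O)(O)=O)C(O)C1O",
                                "CCCO", "CCCCO"),
                     stringsAsFactors = FALSE)
  cal <- calibrateCutoff(m, recs)
  # only the alcA-alcB pair survives hub exclusion
  expect_identical(length(cal$foreground), 1L)
  expect_equal(cal$foreground,
               local({fp <- fingerprintStructures(recs)
                      tanimoto(fp["alcA", ], fp["alcB", ])}))
})

test_that("nearest-neighbor mapping ranks model partners above the cutoff", {
  detected <- data.frame(id = c("pentanol", "outlier"),
                         smiles = c("CCCCCO", "c1ccccc1"),
                         stringsAsFactors = FALSE)
  modelRecs <- data.frame(id = c("butanol", "hexanol", "acid"),
                          smiles = c("CCCCO", "CCCCCCO", "CC(=O)O"),
                          stringsAsFactors = FALSE)
  nn <- nearestModelNeighbors(detected, modelRecs,
                              similarityConfig(cutoff = 0.4))
  hits <- nn[nn$query_id == "pentanol", ]
  expect_true(all(c("butanol", "hexanol") %in% hits$model_id))
  expect_true(all(diff(hits$tanimoto) <= 0))
  expect_false("outlier" %in% nn$query_id)
  # an impossible cutoff empties the result
  nn9 <- nearestModelNeighbors(detected, modelRecs,
                               similarityConfig(cutoff = 0.99))
  expect_identical(nrow(nn9), 0L)
  # empty query list
  nn0 <- nearestModelNeighbors(detected[0, ], modelRecs, similarityConfig())
  expect_identical(nrow(nn0), 0L)
})

test_that("spectral index lookup matches full key first, block as fallback", {
  idx <- data.frame(
    inchikey = c("LFQSCWFLJHTTHZ-UHFFFAOYSA-N", "BDERNNFJNOPAEC-UHFFFAOYSA-N",
                 "LFQSCWFLJHTTHZ-UHFFFAOYSA-N"),
    method = c("LC-MS", "GC-MS", "NMR"),
    source = "fixture", stringsAsFactors = FALSE)
  recs <- data.frame(
    id = c("etoh", "proh", "missing", "stereo"),
    inchikey = c("LFQSCWFLJHTTHZ-UHFFFAOYSA-N", "BDERNNFJNOPAEC-UHFFFAOYSA-N",
                 "ZZZZZZZZZZZZZZ-UHFFFAOYSA-N", "LFQSCWFLJHTTHZ-ABCDEFGHSA-N"),
    stringsAsFactors = FALSE)
  av <- lookupIndex(recs, idx)
  expect_true(av[av$id == "etoh", "LC-MS"])
  expect_true(av[av$id == "etoh", "NMR"])
  expect_false(av[av$id == "etoh", "GC-MS"])
  expect_false(av$block_fallback[av$id == "etoh"])
  expect_false(any(unlist(av[av$id == "missing",
                             c("LC-MS", "GC-MS", "CE-MS", "NMR")])))
  # connectivity-block fallback is flagged
  expect_true(av[av$id == "stereo", "LC-MS"])
  expect_true(av$block_fallback[av$id == "stereo"])
  # count verified by direct scan
  panel <- makeStructurePanel(seed = 8, n_model = 10, n_detected = 4,
                              overlap_fraction = 0)
  recs2 <- panel$modelRecords
  idx2 <- data.frame(inchikey = recs2$inchikey[c(1, 3, 5, 7)],
                     method = "LC-MS", source = "fixture",
                     stringsAsFactors = FALSE)
  av2 <- lookupIndex(recs2, idx2)
  expect_identical(sum(av2[["LC-MS"]]),
                   sum(recs2$inchikey %in% idx2$inchikey))
  expect_identical(sum(av2[["LC-MS"]]), 4L)
})
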