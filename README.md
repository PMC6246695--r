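# gsmtools

Merging, flux audit and metabolome coverage for genome-scale metabolic
models, written for consensus-reconstruction work of the kind behind the
*Caenorhabditis elegans* community models.

Independently built metabolic reconstructions of the same organism
disagree: they use different gene and metabolite namespaces, carry the
same reaction twice with different proton bookkeeping, and attach
different gene rules to the same chemistry. Building a consensus model
means reconciling identifiers, detecting duplicate reactions
stoichiometrically, merging gene associations without losing isoenzymes,
and checking after every merge that the model can still grow. Once
merged, the model has to face experimental reality: which of the
metabolites that metabolomics actually detects in the organism does the
model contain?

`gsmtools` implements that pipeline as an R package:

* **Model core** — an S4 `GSModel` container with readers/writers for
  SBML Level 2 (COBRA-notes dialect), SBML Level 3 + FBC, and SBtab TSV
  spreadsheets; structural validation (`validateModel`).
* **Reconciliation** — gene/metabolite identifier mapping against frozen
  local tables (`mapGeneIds`, `normalizeMetaboliteIds`), duplicate
  metabolite merging (`deduplicateMetabolites`), and elemental/charge
  balance checking (`checkBalance`): the imbalance of a reaction is
  `sum_i nu_i * formula_i` over products and substrates, with generic
  groups R/X conserved like elements.
* **Merge engine** — canonical orientation-normalized reaction signatures
  (`canonicalSignature`), proton-stripped rematching (`stripProtons`),
  duplicate removal with balance arbitration (`deduplicateReactions`),
  GPR OR-merging in canonical DNF (`gprOrMerge`), and a viability-guarded
  iterative merge (`guardedMerge`) that reverts any removal after which
  the biomass reaction can no longer carry flux in a free-growth FBA.
* **Flux analysis** — FBA (`max c.v` s.t. `S v = 0`, `lb <= v <= ub`),
  flux variability, blocked-reaction detection (`findBlocked`) and
  metabolite producibility (`producible`).
* **Structure matching** — InChIKey connectivity-block entities
  (`inchikeyBlock1`), 1024-bit path fingerprints, Tanimoto similarity
  `T = |a AND b| / |a OR b|` with cutoff calibration from reaction pairs
  (`calibrateCutoff`, default cutoff 0.4), model-vs-detected coverage
  partitions (`coverage`) and nearest-model-neighbor mapping for
  detected-only metabolites (`nearestModelNeighbors`).
* **Pathway templates** — programmatic builders for the phenomenological
  glycogen cycle (`glycogenModule`), ascaroside biosynthesis with
  peroxisomal beta-oxidation (`ascarosidePathway`) and maradolipid
  acylation (`maradolipidModule`).
* **Synthetic fixtures** — seeded generators of toy networks, duplicate-
  planted model pairs and structure panels (`makeToyNetwork`,
  `makeDuplicatePair`, `makeStructurePanel`), so the whole pipeline is
  testable offline.

For context: in the published consensus work this class of merge removed
611 duplicate reactions from a union of 3878 (2355 metabolites, 1537
genes, 3267 final reactions), numbers that depend on the original model
files and dated identifier downloads and are therefore not reproduced
here.

## Worked example

Plant duplicates between two models, merge, and audit:

```r
library(gsmtools)

d <- makeDuplicatePair(seed = 1, n_core = 8, n_exact = 3, n_proton = 2, n_gpr = 1)
cc <- concatModels(d$model1, d$model2)
res <- deduplicateReactions(cc$model, primary_source = "m1")
res$report
#> MergeReport
#>   union sizes: 27 metabolites, 12 genes, 16 reactions
#>   duplicates removed: 6 (GPR OR-merged: 1, balance-corrected: 0)
res$report@removedPairs
#>   kept_id removed_id match_mode gpr_merged balance_winner
#> 1    R1_1       R2_1      exact      FALSE           <NA>
#> ...
#> 4    R1_4       R2_4     proton      FALSE          first
#> 6    R1_6       R2_6      exact       TRUE           <NA>
```

All six planted duplicates are recovered: exact copies are dropped, the
proton variants are matched after proton stripping and resolved toward
the elementally balanced version (`balance_winner = "first"`), and the
copy with a different gene rule has its rule OR-merged into the survivor
(`gpr_merged = TRUE`).

Flux audit of a seeded toy network:

```r
toy <- makeToyNetwork(seed = 7, n_chain = 6, n_blocked = 3, bottleneck = 10)
fba(toy$model, "BIOMASS")$objective
#> [1] 10            # the planted bottleneck
findBlocked(toy$model)
#> [1] "DEAD1" "DEAD2" "DEAD3"
```

The glycogen template:

```r
frag <- glycogenModule()
frag$model
#> GSModel: glycogen_module
#>   metabolites:  14
#>   reactions:    9
```

Nine reactions over six glycogen forms; one full synthesis consumes 12
UDP-glucose and one full breakdown returns 11 glucose-1-phosphate plus 1
glucose — the 12 = 11 + 1 residue ledger is asserted numerically in the
test suite, and every reaction is elementally balanced (glycogenin is
carried as an R-group species).

A command-line front end over the same functions is included:

```sh
Rscript inst/cli/gsmtool.R template glycogen --out glycogen.xml
Rscript inst/cli/gsmtool.R merge m1.xml m2.xml --out merged.xml --report report.tsv
Rscript inst/cli/gsmtool.R blocked merged.xml --tol 1e-6
```

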