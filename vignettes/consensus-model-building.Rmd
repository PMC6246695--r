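---
title: "Building and auditing consensus metabolic models with gsmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and auditing consensus metabolic models with gsmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmtools)
```

## The problem

Several genome-scale reconstructions of *C. elegans* metabolism were
built independently, on different software stacks and different
identifier namespaces. A consensus model has to union their content
without double-counting: the same biochemical reaction typically appears
in both parents, sometimes verbatim, sometimes differing only in proton
bookkeeping (a consequence of inconsistent protonation-state
conventions), and sometimes with different gene assignments for the same
chemistry. This vignette describes the procedure the package implements,
the choices made where the design was genuinely open, and what the test
suite does and does not establish.

## The model container

A `GSModel` holds compartments, metabolites (with optional Hill formula
and integer charge, plus database annotations), reactions (signed
stoichiometry maps, flux bounds in the conventional mmol/gDW/h units,
gene rules, provenance tags) and a gene set. Structural invariants —
every stoichiometry key resolves, every gene-rule leaf is declared,
bounds are ordered — are enforced by `validateModel()`, which returns a
typed issue list rather than throwing, so curation workflows can triage.

Reaction coefficients are stored as R doubles and compared exactly in
signatures. Model coefficients are in practice small integers or simple
fractions (halves, tenths), which doubles represent exactly; serializers
write the shortest decimal that round-trips, so values survive SBML and
SBtab round trips bit-identically. We chose doubles over a rational
type because no coefficient arithmetic in the pipeline (signature
comparison, balance summation) can introduce rounding at these
magnitudes, and doubles keep the stoichiometric matrix directly usable
by the LP layer.

Interchange formats follow the community conventions: SBML Level 3 with
the flux-balance-constraints package (bounds as parameters, gene
associations as `fbc:geneProductAssociation` trees, objectives as flux
objectives), SBML Level 2 in the historical COBRA dialect
(`LOWER_BOUND`/`UPPER_BOUND` kinetic-law parameters,
`GENE_ASSOCIATION:` notes), and SBtab TSV for human curation. The SBtab
column set (Compound, Reaction, Gene tables; arrow equations with
`<=>`/`=>` encoding reversibility) is a minimal reconstruction of the
spreadsheet convention; no published enumeration of the customized
variant exists, so the tables here carry exactly the fields the model
container needs and round-trip losslessly.

## Gene rules

Gene-protein-reaction rules are boolean expressions over genes: OR for
isoenzymes, AND for complex subunits. The canonical form used everywhere
is disjunctive normal form — a sorted set of sorted gene sets with
absorbed terms removed — which makes rule equality decidable by
comparison and makes the OR-merge of two reactions' rules a set union
followed by re-canonicalization. The test suite checks DNF soundness by
exhaustive truth-table enumeration (independent of the parser) on rules
of up to 10 genes.

## Duplicate detection

The merge concatenates two reconciled models (`concatModels`), tagging
every reaction with its model of origin, then scans with first-model
primacy (`deduplicateReactions`): for each first-model reaction, each
remaining second-model reaction is compared by canonical signature.

The signature sorts participants by compartment-stripped metabolite key,
and for reversible reactions normalizes orientation so that the
lexicographically smallest participant carries a negative sign — a
reaction and its reverse are then indistinguishable, while irreversible
reactions keep their direction (an irreversible A→B is deliberately not
matched to an irreversible B→A, since those encode different
biochemistry). Coefficients are compared exactly with no rescaling:
2A→2B is not A→B. Treating scaled variants as duplicates would be a
stronger claim than stoichiometric identity supports, so they are left
to manual curation.

On an exact match the second copy is removed; if the gene rules differ,
they are first OR-merged into the survivor (the isoenzyme
interpretation of two models asserting different genes for the same
chemistry). If no exact match exists, signatures are recompared after
removing protons (per-compartment proton ids, configurable, default
`h_c`, `h_m`, `h_n`, `h_e`; water is deliberately not stripped). A
proton-stripped match means the two models disagree about protonation,
so elemental balancing arbitrates: the balanced version's stoichiometry
survives, and when the second model's version is the correct one its
stoichiometry and meta information replace the first's. If both versions
are unbalanced the pair is kept and flagged for manual curation rather
than guessed at. Biomass reactions are never removed — both parents'
biomass functions are kept for later evaluation.

## Viability-guarded merging

Some merges that look safe stoichiometrically still disconnect the
biomass function. `guardedMerge()` therefore applies candidate removals
one at a time; after each, the model must achieve objective flux above
tolerance (default 1e-6 flux units) in a free-growth FBA — every
exchange reaction opened to (−1000, 1000). A failing merge is reverted
and recorded. The free-growth convention is used because a merge should
be judged on network connectivity, not on whichever medium the bounds
happened to encode.

## Flux analysis

The LP core maximizes `c·v` subject to `S·v = 0` and bounds. Flux
variability ranges each reaction without fixing an objective, matching
the "can this reaction carry flux at all" question; a reaction is
blocked when both extrema are within tolerance of zero. Reversible
reactions are not split; ranges are signed. Only optima and ranges are
contractual — LP degeneracy means the returned flux vector is any
optimal vertex.

Bounded-variable LPs are solved through `pracma::linprog` behind a thin
standard-form wrapper (shift to non-negative variables, upper bounds as
inequality rows, objective corrected by `c·lb`). The big-M phase of
that solver is sensitive to the penalty magnitude — a penalty that is
too close to the active bound scale can render the working basis
numerically singular — so the wrapper retries over a ladder of
penalties (1e3 to 1e7) before declaring a problem infeasible. The test
suite cross-checks optima, ranges and blocked sets against an
independent interior-point/simplex implementation (scipy's HiGHS) on
every fixture.

## Structure-level comparison

Model-vs-measured comparison works on InChIKey connectivity blocks: the
first 14 characters hash the atom-connectivity layer only, so
stereoisomers (glucose-6-phosphate vs galactose-6-phosphate) and
protonation variants collapse into one *entity*. This deliberately
ignores stereochemistry, because reported detections often cannot
resolve it; the price is that genuinely distinct stereoisomers count
once. Records without a key (including generic R-group structures,
which have no concrete connectivity) are counted separately and excluded
from the partition.

Similarity uses 1024-bit path-based fingerprints (Open Babel FP2, linear
fragments up to seven atoms, hashed) and Tanimoto similarity. The
default relatedness cutoff is 0.4; because absolute Tanimoto values are
fingerprint-dependent, the cutoff is explicitly configurable, and
`calibrateCutoff()` recomputes the supporting evidence on any model: the
foreground distribution of substrate–product pairs across reactions
(hub/currency metabolites excluded — water, protons, adenosine
phosphates, CoA, redox carriers, phosphates and the like, a configurable
list) against the background of all (or sampled, default 100000,
seeded) structure pairs. On homologous-series fixtures the foreground
stochastically dominates the background, which is the qualitative
property the cutoff rests on.

## Pathway templates

**Glycogen.** Branching combinatorics make mechanistic glycogen
impossible in a stoichiometric model, and legacy reconstructions often
leak glucose residues around the cycle. The template is a
phenomenological cycle over six glycogen forms and nine reactions, built
so that one full synthesis consumes exactly 12 UDP-glucose and one full
breakdown returns exactly 11 glucose-1-phosphate and 1 glucose, with
exactly one debranching event (the alpha(1,6) bond) per unit and no
maltose reactions. The specific 9-reaction decomposition (primer of 2
residues; elongation ladder 6, 9, 11; branched mature form of 12;
limit dextrin of 7) is one of several decompositions satisfying those
constraints; the constraints, not the decomposition, are the contract,
and the cycle audit (every form returns to net zero; residues in =
residues out) is asserted numerically in the tests. Glycogenin is
carried as an R-group species so that all nine reactions balance
elementally.

**Ascarosides.** The worm-specific glycolipid pheromones are built from
ascarylose attached to an omega- or omega-1-hydroxy fatty acid and
chain-shortened two carbons per round of peroxisomal beta-oxidation.
Since no ascarosyl transferase is known, sugar attachment is a lump
reaction from glucose (the 3,6-dideoxygenation charged to NADPH — a
modelling placeholder reflecting the stated uncertainty in the
biosynthetic route). Each round carries four reactions with the gene
associations acox-1, maoc-1, dhs-28, daf-22 in pathway order, releasing
acetyl-CoA; CoA thioesters are carried at charge −4, with intermediate
protonation states chosen so every step balances (oxidase to enoyl via
O2/H2O2, hydratase, NAD-dependent dehydrogenase releasing a proton,
thiolase). Hydrolysis and extracellular export close each chain length.
Beta-oxidation is placed in the cytosol with a peroxisome-like
subsystem tag, since the four-compartment convention (cytosol,
mitochondrion, nucleus, extracellular) has no explicit peroxisome.

**Maradolipids.** Stepwise 6- and 6'-acylation of trehalose from
fatty-acyl-CoAs, two reactions per acyl pair through the described lyso
intermediate; species formulas are assembled by group arithmetic so both
acylations balance by construction.

## Synthetic fixtures and what the tests show

The generators are pure functions of an integer seed (a small
multiplicative-congruential stream per generator, version-pinned in the
emitted metadata). `makeDuplicatePair` plants exact, proton-variant and
gene-rule-variant duplicates between two models — proton variants are
planted so the first model's copy is the balanced one — with unique
filler reactions on disjoint metabolite pools so no accidental signature
collisions occur. `makeToyNetwork` plants a known FBA optimum (a single
bottleneck bound on an uptake-to-biomass chain) and a known blocked set
(dead-end reactions). `makeStructurePanel` draws from homologous SMILES
series (alcohols and acids on the model side, diols and amines reserved
for the detected side) and plants an exact entity overlap.

Because every planted truth is recovered exactly (100 seeded merge
instances; flux truths cross-checked against an independent LP solver;
coverage partitions on random panels), the suite establishes the
*algorithms*. What it cannot establish is behavior on real
reconstructions: the fixtures have clean namespaces, complete formulas
and no scaled or transport-ambiguous duplicates, so fixture recovery
rates say nothing about how much manual curation a real merge still
needs. The published consensus-scale numbers (611 duplicates removed
from a 3878-reaction union; 685 blocked reactions in the released
model) depend on the original model files and dated identifier-mapping
downloads, and are context rather than reproduction targets here; the
blocked-reaction count in particular is only defined relative to an
exchange-bound convention, which is why `findBlocked()` fixes the
free-growth convention explicitly.

Problem sizes throughout the suite (chains of 4–6 metabolites, merge
fixtures of 10–20 reactions, panels of 6–12 structures) were chosen as
the smallest instances that exercise every code path, keeping the whole
suite deterministic and fast.

## Known limitations

* No automatic formula inference from structures, and no pKa-based
  protonation-state computation: formulas and charges come from
  annotations or mapping tables.
* Cross-compartment duplicate unification, transport-reaction repair and
  nested-reaction detection are out of scope; flagged pairs are left to
  curation.
* Fingerprints are path-based; ring-system-sensitive (circular)
  fingerprints would shift absolute Tanimoto values, which is why the
  cutoff is a parameter rather than a constant.
* The LP layer is a dense simplex — appropriate for curation-scale
  models and fixtures; genome-scale flux variability on thousands of
  reactions would want a sparse solver.
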