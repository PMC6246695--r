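Package: gsmtools
Title: Merging, Flux Audit and Metabolome Coverage for Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building consensus genome-scale metabolic
    reconstructions. Reads and writes constraint-based models in SBML
    (Level 2 with COBRA notes, Level 3 with the flux-balance-constraints
    package) and SBtab spreadsheets; reconciles gene and metabolite
    identifiers against local mapping tables; detects duplicate reactions
    by canonical stoichiometric signatures with proton-stripped rematching
    and elemental-balance arbitration; merges gene-protein-reaction rules
    in disjunctive normal form; performs viability-guarded iterative
    merging; audits models by flux balance analysis, flux variability and
    blocked-reaction detection; and compares model metabolite structures
    against experimentally detected metabolites via InChIKey connectivity
    blocks and Tanimoto fingerprint similarity. Includes programmatic
    builders for curated pathway modules (glycogen cycle, ascaroside
    beta-oxidation, maradolipid acylation) and seeded synthetic fixture
    generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xml2,
    pracma,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
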