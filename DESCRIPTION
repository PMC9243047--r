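Package: nucanomer
Title: Conformer Ensembles and Reaction Thermodynamics of Nucleoside Anomers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the conformational-ensemble thermodynamics of
    nucleoside and nucleotide anomers: randomized dihedral conformer
    sampling over hydroxyl torsions, Boltzmann partition-function conformer
    selection, rigid-rotor harmonic-oscillator (RRHO) thermochemistry,
    relaxed (soft) glycosidic and phosphate torsion scans, and a reaction
    Gibbs-energy ledger comparing two condensation pathways (base-first and
    phosphate-first) and sugar-exchange reactions between uracil and
    thymine nucleotides.  A built-in surrogate potential with a constrained
    local optimizer stands behind a pluggable energy-backend contract, and
    adapters read and write semiempirical and DFT program decks and logs.
    A synthetic-data module generates conformer ensembles and species
    thermochemistry tables with planted, exactly recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
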