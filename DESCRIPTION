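Package: flextail
Title: Crosslink-Restrained Ensemble Modeling of Flexible Protein Tails
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale integrative modeling of flexible terminal regions
    attached to rigid protein cores. Provides conformational sampling of
    C-alpha tail models under flat-harmonic crosslinking mass spectrometry
    (XL-MS) distance restraints, Debye-equation small-angle X-ray scattering
    (SAXS) profile computation with Guinier and chi-square fitting, SEC-SAXS
    frame reduction and multi-state fitting, an energy/chi-square/crosslink
    model-selection cascade with Kabsch superposition and RMSD leader
    clustering, structural metrics (Shrake-Rupley solvent accessibility,
    interface burial, RMSF), and binding/thermal analyses (biolayer
    interferometry 1:1 kinetics, steady-state one-site binding, one-phase
    association, thermal-melt midpoints). A synthetic-data module generates
    every input class with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
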