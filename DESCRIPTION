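Package: porescribe
Title: Quantitative Analysis of Pore-Forming Antimicrobial Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for characterizing oligomeric membrane pores
    formed by transmembrane-helix-containing antimicrobial peptides. Provides
    peptide monoisotopic mass arithmetic and electrospray charge-state
    deconvolution, Kyte-Doolittle hydropathy and amphipathicity analysis,
    stepwise single-channel conductance detection in planar-bilayer
    voltage-clamp recordings, reversal-potential and
    Goldman-Hodgkin-Katz ion-selectivity inference, access-resistance pore
    geometry models, beta-barrel geometry, multimer-model confidence ranking,
    dye-leakage normalization, and a synthetic-data module that generates
    current traces, I/V sets, charge-state spectra and confidence tables with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    seqinr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
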