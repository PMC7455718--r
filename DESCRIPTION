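Package: mtmodkit
Title: Mapping and Quantifying Mitochondrial tRNA Modifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the three computational stages used to chart
    post-transcriptional modifications in human mitochondrial tRNAs:
    in-silico RNase T1/A digestion of modified oligonucleotides with exact
    elemental-formula mass arithmetic, assignment of negative-mode LC-MS/MS
    peaks to theoretical fragments with CID-based modification localization
    and intensity-ratio stoichiometry; the pseudouridine (Psi) score computed
    from CMC-plus/CMC-minus read pileups with the associated read filters and
    site calling; and mitoribosome-profiling codon-occupancy analysis under
    the vertebrate mitochondrial genetic code with per-codon fold-change and
    rank-sum statistics. Seeded synthetic-data generators emulate all three
    input types so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
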