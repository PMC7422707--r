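Package: mepephos
Title: Phosphosite Mapping of MEPE and Its ASARM Motif from Tryptic
    Mass Spectrometry Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping FAM20C-dependent phosphorylation sites on
    secreted phosphoproteins, built around the matrix extracellular
    phosphoglycoprotein (MEPE) study system. Models recombinant constructs
    (point mutations and epitope tags) with faithful coordinate bookkeeping,
    performs in-silico tryptic digestion with missed cleavages, computes
    theoretical peptide masses (monoisotopic and average) with variable
    modifications, assigns MALDI phospho-ladders with mass-tolerance
    matching and dephosphorylation controls, scans sequences for FAM20C
    recognition motifs (Ser-x-Glu, Ser-x-pSer with fixed-point propagation,
    Ser-x-Asp, acidic n+5..n+7 context), scores phosphosite conservation
    across aligned ortholog families, and collates peptide-level evidence
    (with ambiguous site pairs and spectral counts) into residue-level site
    maps with major-site calls. Ships seeded synthetic-data generators and
    an end-to-end reproduction pipeline over packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
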