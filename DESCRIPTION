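Package: gitmicro
Title: Multi-Kingdom Microbiome Profiling of the Ruminant Gastrointestinal Tract
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly analysis toolkit for multi-kingdom (bacterial,
    archaeal, viral) metagenome catalogs of the ruminant gastrointestinal
    tract. Provides genome-level relative-abundance profiling (TPM) with
    taxonomic roll-up, rarefaction curves, qPCR standard-curve
    quantification, community statistics (Bray-Curtis dissimilarity,
    ANOSIM, single- and multi-factor PERMANOVA, an LDA-effect-size
    differential-taxon screen, fuzzy c-means trajectory clustering of
    Firmicutes/Bacteroidota ratios), a genus-by-glycoside-hydrolase
    correlation screen, and a four-evidence virus-host interaction network
    (CRISPR spacer matching, nucleotide homology, d2* oligonucleotide
    dissimilarity, bin co-membership) culminating in a lytic-phage versus
    methanogen screen. Includes a synthetic community generator with a
    machine-readable truth ledger for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    e1071
Config/testthat/edition: 3
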