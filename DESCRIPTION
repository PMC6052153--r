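Package: numtsweep
Title: Pseudogene Screening, Divergence Profiling and Threshold Species
    Delimitation for Mitochondrial Barcode Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing mitochondrial DNA barcode datasets that may
    be contaminated by nuclear mitochondrial pseudogenes (NUMTs) and other
    corrupt sequences. Implements a four-criterion screen for partial
    cytochrome oxidase I (mtCOI) haplotypes (INDELs, premature stop codons,
    anomalous polymorphisms, substitutions at conserved amino-acid sites),
    Jukes-Cantor divergence analysis over fixed barcode regions and sliding
    windows, multigene concatenation of annotated mitogenomes, and
    3.5%-threshold species delimitation with cross-region discordance
    detection. A codon-constrained synthetic-data generator produces
    labelled haplotype groups and NUMT lesion classes so every stage of the
    pipeline can be tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ape,
    igraph,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
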