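Package: tescan
Title: Structural Annotation of TnpB/Fanzor-Associated Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and annotation toolkit for the structural hallmarks of
    TnpB/Fanzor-associated DNA transposons. Scans protein sequences for the
    conserved Fanzor/TnpB residue constellation (a PROSITE-style motif with
    bounded spacers and a C4 zinc finger), finds terminal inverted repeats,
    DNA stem-loops (hairpins) and asymmetric terminal inverted repeat (ATIR)
    pairs at element termini, classifies Helitron candidates into the
    canonical Helitron1 group or the hairpin-flanked Helitron2 group, calls
    variable-length target site duplications (TSDs) at insertion loci with
    target-site preference analysis, profiles 5'-truncation across repeat
    family copies, builds majority-rule family consensus sequences with
    copy-to-consensus identities, and simulates genomes with planted elements
    carrying known structures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
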