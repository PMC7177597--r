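Package: pacfinder
Title: Discovery and Classification of PAC Domain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding PAC (Proline-rich, Arabinogalactan protein,
    Conserved Cysteines) domains in protein sequences by their conserved
    six-cysteine spacing pattern, gating candidates on signal peptide,
    secondary structure and foreign-domain criteria, classifying PAC
    domain proteins into the four canonical domain architectures,
    checking the diagnostic intron position and tandem gene duplications,
    computing global-alignment identity and similarity for deduplication
    and distance matrices, building per-column conservation profiles, and
    validating the Cys1-Cys5/Cys3-Cys4/Cys2-Cys6 disulfide topology and
    solvent accessibility on 3D models. Includes a synthetic-data
    generator that plants ground-truth domains, gene models, tandem
    clusters and structures so every stage of the pipeline can be tested
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    Biostrings,
    rtracklayer,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
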