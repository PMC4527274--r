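Package: cblkit
Title: Characterization of Plant Calcineurin B-Like (CBL) Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based characterization of plant calcineurin B-like (CBL)
    calcium-sensor protein families. Detects 36-residue EF-hand
    helix-loop-helix calcium-binding modules and degenerate conserved motifs,
    classifies CBL candidates by their three-EF-hand architecture, predicts
    N-terminal myristoylation and palmitoylation sites from
    glycine/cysteine position rules, assigns orthology-based gene names with
    species-abbreviation collision resolution and paralog numbering, relates
    amino-acid composition to biosynthetic energy cost, computes Tajima's
    relative rate test and Tajima's D test of neutrality on amino-acid
    alignments, and quantifies relative expression from qPCR Ct tables by
    the 2^-ddCt (Livak) method. Seeded generators produce every input class
    with planted ground truth for validation.
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
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
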