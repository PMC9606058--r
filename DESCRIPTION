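Package: museomt
Title: Mitogenome Reconstruction and Comparison from Degraded Museum Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for museomics: simulate short, deaminated
    sequencing reads from a circular mitochondrial genome with a planted truth
    set, map them back to a circular reference with uniqueness filtering and
    duplicate flagging, profile post-mortem cytosine-deamination damage,
    call a depth- and majority-rule consensus with rotation-based recovery of
    terminal positions and repeat masking, classify differences between
    near-identical mitogenomes (transitions/transversions, codon and
    amino-acid changes under the vertebrate mitochondrial code,
    region-excluded summaries, pairwise-deletion distances), and draw
    haplotype genealogy graphs by Fitch parsimony.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
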