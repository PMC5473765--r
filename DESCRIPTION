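Package: retrochrono
Title: Structural Annotation, Molecular Dating, and Abundance Profiling of
    LTR Retrotransposons
Version: 0.1.0
Authors@R:
    person("Retrochrono", "Developers", email = "retrochrono@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for the evolutionary analysis of
    long-terminal-repeat (LTR) retrotransposons. Detects intact elements
    structurally (paired direct repeats sharing a target-site duplication),
    classifies them into Ty1-copia / Ty3-gypsy superfamilies by pol-domain
    order, clusters elements into families by 5'-LTR identity, dates each
    insertion from LTR-pair divergence under a molecular clock (T = K/2r),
    builds neighbor-joining phylogenies of reverse-transcriptase domains,
    and estimates per-family copy number from normalized short-read depth
    over a deduplicated LTR library. Ships a synthetic-genome generator
    that plants elements of known family structure, age, and copy number so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
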