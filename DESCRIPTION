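Package: pharmacobiome
Title: Drug-Mimicry Screening of Microbiome-Associated Host Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Connectivity-map-style screening of host-microbiome multi-omics
    data. Derives per-microbe and per-metabolite host gene signatures from
    paired expression, taxon-abundance and metabolite matrices using Spearman
    and covariate-adjusted partial Spearman correlation with Benjamini-Hochberg
    correction; scores the directional similarity of those signatures to
    drug-perturbation up/down gene sets with Fisher's exact test; clusters and
    ranks the resulting microbe/metabolite-drug mimicry pairs. Includes a
    synthetic multi-omics cohort generator with planted effects, confounding
    and mimicry structure for end-to-end validation, plus a simple
    produced/consumed classifier for culture metabolomics profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    pheatmap,
    ape
Config/testthat/edition: 3
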