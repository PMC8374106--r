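Package: mchhislands
Title: Detection and Comparative Analysis of Upstream mCHH Methylation Islands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical detection of mCHH methylation islands in plant
    whole-genome bisulfite data and analysis of their genic and evolutionary
    correlates. Calls islands as 100 bp windows whose CHH methylation exceeds
    the genome-wide background by a one-sided binomial test with
    Benjamini-Yekutieli false discovery control, associates islands with genes
    through strand-aware 2 kb flanks, derives genic predictors (distance to the
    nearest transposable element, gene length, expression quartile, gene-body
    methylation) for logistic-regression modelling with variable-importance
    scores, quantifies cross-species conservation of island state over
    one-to-one orthologs with permutation nulls, tests transposable-element
    superfamily enrichment, and generates fully synthetic multi-species
    methylomes with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    jsonlite
Config/testthat/edition: 3
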