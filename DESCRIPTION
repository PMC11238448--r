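Package: herdstruct
Title: Fine-Scale Population Structure, Admixture and Runs of
    Homozygosity from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the fine-scale structure of closed
    livestock breeds from dense SNP genotypes: identity-by-state
    relationship matrices, principal component analysis, Weir-Cockerham
    F_ST, supervised and unsupervised admixture estimation by EM with
    masking-based cross-validation, Horn's parallel analysis and
    SVD-based genetic contribution scores, k-nearest-neighbour
    population networks, PLINK-semantics detection of runs of
    homozygosity with genomic inbreeding (F_ROH) and ROH islands, and
    pedigree-based inbreeding and admixture for genomic-vs-pedigree
    comparisons.  Includes a gene-dropping simulator with known
    ancestry and autozygosity ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
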