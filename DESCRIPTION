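Package: pleionet
Title: Cis- and Trans-Regulatory Pleiotropy in Gene-Deletion Perturbation
    Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds directed perturbation networks from gene-deletion
    expression compendia (log2 fold-changes and FDR-adjusted p-values per
    deletion strain), treats each deleted gene in turn as a focal gene, and
    compares the pleiotropy of the cis-acting deletion of the focal gene
    with the trans-acting deletions that alter its expression. Pleiotropy
    is measured as differentially expressed gene counts, as counts with
    nested effects removed, and as Euclidean distance from wild type in
    expression space. Includes degree-preserving and fully randomizing
    edge-permutation null models, log-log least-squares power-law fits of
    the out-degree distribution, deletion-fitness integration, and a
    seeded synthetic-data generator that emulates the compendium's
    statistical structure so the entire pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
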