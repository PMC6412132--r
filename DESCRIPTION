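Package: yome
Title: Consensus Determination of Poorly Annotated Genes (the y-ome) from
    Multiple Knowledge Bases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Integrates gene-function annotations from multiple curated
    knowledge bases, categorizes each gene per source with a data-driven
    keyword and structured-data rule engine, and resolves a final category
    (y-ome, well-annotated, or excluded) with agreement-based consensus
    rules, exception heuristics for high-trust evidence, and a manual
    curation override layer. Includes the downstream analyses used to
    characterize the resulting gene set: expression stratification from a
    counts matrix (TPM, log-TPM, replicate correlation QC, Welch contrast),
    circular chromosome density with a von Mises kernel, co-expression
    module composition, term-frequency tables, and naming-convention
    cross-tabulation. A synthetic-data generator with planted ground truth
    makes every stage testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
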