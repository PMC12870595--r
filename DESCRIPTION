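Package: simpheny
Title: Phenotype-First Patient Matching and Candidate Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ontology-based phenotype-first matching of query patients against
    a diagnosed reference cohort for rare-disease gene prioritization.
    Implements an information-content-weighted Jaccard similarity over
    self-inclusive ancestor sets of phenotype-ontology terms (PhenoSimJaccard),
    best-match-average aggregation to term-set similarity (funSimAvg),
    Monte-Carlo empirical null distributions yielding phenotype and gene
    p-values, their combination with Empirical Brown's Method into a SimPheny
    Score with confidence tiers, gene-level ranking, and benchmarking surfaces
    (ROC/auROC and FDR-TPR curves over score thresholds). Includes a synthetic
    ontology and cohort generator so every component is testable without
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
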