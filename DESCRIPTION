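Package: lymphomine
Title: Mutation Co-Occurrence Mining and Genetic Subtyping of Relapsed/Refractory DLBCL Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Harmonizes multi-study somatic mutation call tables into a
    patients-by-genes binary alteration matrix, mines gene co-mutation
    structure with the apriori algorithm (support, confidence, lift),
    clusters genes on anchor-gene lift profiles with a self-organizing map,
    assigns a rule-based five-subtype genetic classification
    (JAK-STAT, BCL2-CREBBP, MCD, TP53-independent, sparse), and compares
    therapy response and overall survival across subtypes. Includes a
    synthetic-cohort generator with planted co-mutation blocks for
    validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    survival,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
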