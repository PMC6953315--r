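Package: electroDGE
Title: Differential Expression and Phenotype-Consistent Gene Sets for
    Electric-Organ Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Count-level differential-expression pipeline for comparing
    electric-organ transcriptomes across mormyrid operational taxonomic
    units (OTUs): TMM normalization, pairwise negative-binomial exact
    tests with conditional-likelihood dispersion estimation, a nested
    gene-set procedure (Set A union, informative-comparison Set A',
    phenotype-consistency Set B, intersection Set C) that maps
    differentially expressed genes onto electric-organ-discharge
    waveform features (duration, polarity, complexity), and DAG-aware
    Gene Ontology enrichment with elim-style decorrelation. Includes a
    negative-binomial count simulator with planted phenotype-linked and
    OTU-specific genes so the full procedure can be exercised and its
    operating characteristics measured without any sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
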