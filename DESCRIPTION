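Package: GOgrouper
Title: Gene Ontology Enrichment Analysis with Two-Step GO Grouping
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for gene ontology enrichment analysis (GOEA) and for
    organizing its results. Parses OBO 1.2 ontologies into a validated
    directed acyclic graph with typed edges, reads annotations in GAF,
    NCBI gene2go and GPAD formats, and tests study gene sets for over- and
    under-represented terms with a two-sided Fisher's exact test and a
    family of multiple-test corrections (Bonferroni, Sidak, Holm,
    Benjamini-Hochberg, Benjamini-Yekutieli, resampling FDR). Provides
    per-term specificity metrics (depth, level, descendant counts,
    information content, Resnik and Lin semantic similarity, GO-slim
    mapping), a two-step grouping method that files enrichment results
    under broad GO headers and researcher-named sections, hierarchy and
    DOT reports, and a stochastic simulation framework that measures
    gene-level false discovery rate, sensitivity and specificity of GOEAs
    on synthetic skewed associations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
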