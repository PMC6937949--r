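Package: varitriage
Title: Knowledge-Driven Clinical Variant Triage and Reporting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale clinical genome interpretation workflow: VCF
    sanitization and normalization, transcript-aware consequence calling,
    automated ACMG/AMP 2015 evidence assignment and five-class pathogenicity
    combination, phenotype-keyword gene prioritization over a sectioned gene
    knowledgebase with highlighted evidence snippets, inheritance-model filter
    cascades for singleton and trio exomes (dominant, recessive homozygous,
    compound heterozygous, incidental findings), structural-variant mapping to
    genes and regulatory elements with combined confidence-phenotype scoring,
    a persistent case store with in-house allele frequencies and account
    resolution statistics, and versioned JSON/Markdown clinical reports.
    All knowledgebase content is emulated by a built-in synthetic fixture
    generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
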