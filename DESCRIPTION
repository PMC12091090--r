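Package: translens
Title: Cross-Dataset Translatome Comparison and CDS-Length Shift Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Compares differential-translation profiles across TRAP-seq
    (translating ribosome affinity purification) datasets. Provides paired
    differential-translation estimation with median-of-ratios normalization
    and the 10-counts-in-3-samples expression filter, stimulation-specific
    set construction, percent-overlap and sign-concordance statistics with
    hypergeometric overlap significance, cross-dataset fold-change
    association with linear and penalized-spline fits, coding-sequence
    length binned z statistics and length-fold-change correlation,
    classic-statistic preranked gene-set enrichment with permutation NES
    and FDR, hypergeometric over-representation, GMT and tab-separated
    table input/output, and a seeded negative-binomial synthetic-data
    generator with known ground truth so the whole pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
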