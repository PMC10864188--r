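Package: pamlcat
Title: Molecular Categorization and Risk Stratification of Pediatric Acute Myeloid Leukemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor-only variant screening, allele-specific expression testing,
    a mutually exclusive 23-category molecular classifier, HOXA/HOXB
    superfamily grouping, co-occurrence statistics, and a category-by-MRD
    six-stratum prognostic framework for pediatric acute myeloid leukemia
    (pAML). Includes a seeded synthetic-cohort generator that emulates the
    genomic, transcriptomic and survival structure the analyses assume, so
    the whole pipeline can be exercised and tested without access to
    protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    vcfR,
    Matrix,
    jsonlite
Config/testthat/edition: 3
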