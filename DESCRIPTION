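Package: hbocclassify
Title: Automated ACMG/AMP Germline Variant Classification for
    Hereditary Breast and Ovarian Cancer Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based engine applying the ACMG/AMP germline variant
    classification criteria with gene-specific schemes for the
    hereditary breast and ovarian cancer (HBOC) genes ATM, BRCA1,
    BRCA2, CDH1, PALB2, PTEN and TP53.  Evidence is evaluated in
    separate protein and splicing channels, combined with both the
    original class-combining rules and the additive point-based
    system, and merged into a single final five-tier class.  Includes
    input validation with left normalization of indels, a YAML-driven
    scheme registry, JSON and VCF output, a command-line interface,
    and a deterministic synthetic-fixture generator with an
    independent straight-line expectation oracle for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
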