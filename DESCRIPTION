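Package: steplink
Title: Stepwise Deterministic Record Linkage with Privacy-Preserving Composite Keys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a cohort roster to a de-identified hospital-admissions
    person index using a stepwise deterministic strategy: an ordered plan of
    composite-key iterations built from a truncated national health-insurance
    number, a three-letter given-name suffix, and demographic variables
    (date-of-birth components, sex, country of birth, postcodes). Keys are
    compared as keyed cryptographic digests so that linkage units never
    exchange reversible identifiers. Includes the published three-stage
    iteration plans, agreement analysis between linkage runs, gold-standard
    sensitivity validation with Wilson confidence intervals, and a synthetic
    cohort/hospital data generator with a configurable data-entry error model
    and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    openssl,
    readr,
    tibble,
    yaml
Suggests:
    digest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
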