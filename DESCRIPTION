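Package: dosetrans
Title: Preclinical-to-Clinical Dose Translation for Oncology Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Translates efficacious doses from mouse tumor-xenograft studies
    into predicted human clinical doses using body surface area (BSA)
    conversion for small molecules and direct body-weight (mg/kg) carryover
    for large molecules, and retrospectively evaluates prediction accuracy as
    the fraction of drugs whose predicted dose falls within 2-fold or 3-fold
    of the recommended clinical dose. Provides a validated CSV schema for
    curated drug records, class-level accuracy summaries, log-log scatter
    exports with 3-fold reference bands, bootstrap confidence intervals, and
    a calibrated log-normal fold-error simulator so the full pipeline can be
    exercised on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
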