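Package: dosepath
Title: Organ Dose Accounting and NTCP Risk Modelling Across the
    Radiotherapy Imaging Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying normal-tissue exposure across a
    radiotherapy workflow: calibration of optically stimulated
    luminescence (OSL) dosimeter counts to absorbed dose with
    multiplicative correction factors and uncertainty propagation,
    cumulative imaging-dose accounting over a planning CT and repeated
    cone-beam CT (CBCT) acquisitions with percent-of-prescription
    reporting, dose-volume histogram (DVH) metrics, Niemierko
    equivalent uniform dose (EUD), sigmoidal normal tissue complication
    probability (NTCP) modelling with two-point parameter inversion,
    and technique-comparison matrices. Includes a seeded synthetic-data
    generator (noisy OSL counts, organ dose tables, parametric DVHs) so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
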