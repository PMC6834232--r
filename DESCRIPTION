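Package: apneascreen
Title: Overnight Oximetry Screening for Central Sleep Apnea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening central sleep apnea from overnight pulse
    oximetry. Detects oxygen desaturation dips (>=3 percentage-point drops
    below baseline sustained >=10 s), computes the oxygen desaturation index
    (ODI) and nightly saturation summaries under two baseline conventions,
    classifies scored respiratory-event lists into none / obstructive /
    central sleep apnea by the AHI >= 15 and >=50 percent-central rules, and
    evaluates paired screen-versus-reference agreement (2x2 tables, exact and
    continuity-corrected McNemar tests, sensitivity/specificity/PPV/NPV,
    Bland-Altman limits of agreement, and sample-size calculation for paired
    proportions). Includes a synthetic overnight-oximetry cohort generator
    with ground-truth annotations, emulating Cheyne-Stokes desaturation
    trains, obstructive event clusters, oximeter quantization, noise and
    dropout artifacts, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
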