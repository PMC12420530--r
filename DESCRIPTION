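Package: cobraplan
Title: Co-60 HDR Brachytherapy Dose Calculation, Plan Metrics and Uncertainty Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale dosimetry pipeline for Cobalt-60 high-dose-rate
    intracavitary brachytherapy of cervical cancer. Implements a TG-43
    line/point-source dose engine over tandem-and-ovoids applicator
    geometries, Manchester Point A prescription and plan normalization,
    synthetic pelvic phantom cohorts (HR-CTV plus bladder, rectum, sigmoid
    and bowel), dose-volume histogram metrics (D90, D80, D2cc, V100/V150/V200),
    plan quality indices (CI, COIN, DHI, DNR, ODI), EQD2 dose accumulation
    and constraint auditing, and a rigid-body applicator-displacement and
    TPS-variability uncertainty framework with cohort summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
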