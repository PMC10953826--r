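Package: admscreen
Title: Organoid Morphology Screen Analytics for Acinar-Ductal Metaplasia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analytics for medium-throughput phenotypic drug
    screens that read out acinar-to-ductal metaplasia (ADM) in pancreatic
    organoid cultures. Provides a synthetic-data generator for two-channel
    well images, per-object tables, qPCR CT tables and differential-
    expression tables; organoid segmentation, shape-feature extraction,
    duct/cluster classification and calcein-based viability scoring;
    plate statistics with Welch tests, Z-prime quality control and
    three-criterion hit selection; four-parameter logistic dose-response
    fitting with IC50 reporting; and molecular endpoints including
    2^-delta-delta-CT fold changes, the ADM Reversal Index (ADMRI) and
    volcano-style gene-panel annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    minpack.lm,
    jsonlite,
    tiff,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: CellBasedAssays, Software, Visualization
RoxygenNote: 7.3.3
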