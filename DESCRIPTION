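Package: ctcQuant
Title: Multiplexed Circulating Tumor Cell Immunofluorescence Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed immunofluorescence assays of
    circulating tumor cells (CTCs) in clear cell renal cell carcinoma. Turns
    multichannel fluorescence fields (nuclear stain, CAXII, pan-cytokeratin,
    a pooled leukocyte/endothelial exclusion channel, and one checkpoint or
    antigen-presentation biomarker) into per-cell measurements via
    rolling-ball background subtraction, nucleus-anchored segmentation and
    ring-inclusive quantification; fits flow-cytometry-style positivity
    cutoffs by one-dimensional two-cluster partitioning; classifies cells
    into CTC phenotypes (CAXII single-positive, double-positive, CK
    single-positive) under an exclusion-first rule; scores PD-L1/HLA-I per
    CTC subpopulation; and performs sample-level enumeration, group
    comparison, ROC analysis with likelihood-ratio-optimal cutoffs, and
    longitudinal threshold-crossing reports. A seeded synthetic-data
    generator produces ground-truthed fields, cell tables, cohorts and
    longitudinal series so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    EBImage,
    tiff,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
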