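Package: budconsensus
Title: Tumor-Bud Candidate Detection and Multi-Observer Consensus for
    Pan-Cytokeratin IHC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for individual tumor-bud candidate analysis on
    pan-cytokeratin immunohistochemistry images: color deconvolution of
    hematoxylin/DAB stains, DAB segmentation and connected-component area
    filtering, stratified sampling and review-patch extraction, fusion of
    multi-observer categorical ratings (tumor bud / poorly differentiated
    cluster / neither) under a 70%-majority voting rule, and interobserver
    agreement statistics (Fleiss and Cohen kappa with Landis-Koch
    interpretation). Includes a synthetic-data module that simulates
    stain-realistic brightfield tiles via a Beer-Lambert forward model and
    rater panels with controlled latent structure, so every stage is
    testable without whole-slide images or a pathologist panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
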