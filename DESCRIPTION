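Package: rppgroi
Title: Anatomical ROI Assessment for Facial-Video Remote Photoplethysmography
Version: 0.1.0
Authors@R:
    person("rppgroi", "maintainers", email = "maintainers@rppgroi.dev",
           role = c("aut", "cre"))
Description: Tools to assess facial regions of interest (ROIs) for remote
    photoplethysmography (rPPG). Packages cadaveric facial skin-thickness
    tables and a 31-region anatomical ROI set, rasterizes region masks from
    468-point face-mesh landmarks, implements seven classical pulse-extraction
    algorithms (GREEN, ICA/JADE, CHROM, POS, SSR, PBV, LGI) with windowed
    Welch heart-rate estimation, scores regions with MAE/RMSE/PCC and a
    composite relative BVP-similarity (rBS) metric with median ranking, and
    generates synthetic facial scenes with a planted blood-volume pulse whose
    regional amplitude decreases with skin thickness, for end-to-end
    benchmarking without access to real datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
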