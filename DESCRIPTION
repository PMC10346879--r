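Package: dmhre
Title: Dual-Modality RGB-NIR Remote Photoplethysmography and Heart-Rate
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recovers the remote photoplethysmogram (rPPG) from multi-channel
    facial mean-intensity time series (R, G, B and optionally near-infrared)
    and reads the heart rate from its spectral peak. The denoising chain
    combines amplitude-selective spectral filtering driven by the NIR band,
    CIELab chrominance fusion, stationary wavelet denoising (sym4),
    robust principal component analysis by principal component pursuit, and
    JADE independent component analysis with periodicity-based component
    selection. Includes a frame-sequence frontend with pluggable face
    detection and skin masking, evaluation metrics (MAE, RMSE, SD and the
    5-bpm accuracy), and a seeded synthetic clip generator so the whole
    pipeline is testable without video datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    grDevices,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
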