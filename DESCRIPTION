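Package: SISHscore
Title: Automated HER2 Amplification Scoring from Brightfield SISH Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies HER2 gene amplification from silver in situ
    hybridization (SISH) regions of interest. Detects HER2 (black) and
    CEP17 (red) probe signals by color thresholding inside segmented
    nuclei, applies nucleus qualification rules (at least two CEP17
    signals with a single-CEP17 fallback, exclusion of border-truncated
    and heavily overlapping nuclei), selects representative nuclei by
    their HER2-CEP17 differentiation value, and computes the HER2/CEP17
    ratio, HER2 copies per nucleus and an amplification status following
    ASCO/CAP-style thresholds. Includes a pluggable nucleus segmentation
    backend (classical watershed default), a seeded synthetic SISH scene
    generator with exhaustive ground truth, Bland-Altman method
    comparison statistics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    jsonlite,
    yaml,
    withr,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
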