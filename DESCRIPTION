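Package: fuzzedge
Title: Fuzzy Rule-Based Edge Detection for Smooth and Noisy Greyscale Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mamdani fuzzy-inference edge detection for 8-bit greyscale
    images, designed for impulse-noise robustness in clinical imagery. A 3x3
    difference mask feeds a 12-rule knowledge base over Lower/Higher
    trapezoidal memberships; centroid defuzzification yields a per-pixel edge
    score that is binarized into an edge map. Includes a fuzzy contrast
    intensification pre-stage for smooth low-contrast images, PSNR-calibrated
    salt-and-pepper noise injection, classical baseline detectors (Sobel,
    Prewitt, Roberts, Laplacian-of-Gaussian, Canny), a false-edge /
    sensitivity / specificity evaluation harness, and deterministic synthetic
    fixtures with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
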