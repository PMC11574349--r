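Package: optoquant
Title: Quantification of Optogenetic Morphogen Perturbation Movies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify live-imaging experiments in which nuclear
    levels of a morphogen transcription factor are acutely perturbed by
    light-inducible nuclear export or degradation. Includes detection and
    counting of MS2/MCP transcription-site foci with a two-threshold scheme,
    nuclei segmentation and nearest-neighbour tracking with gap closing,
    single-exponential recovery fitting for FRAP and nuclear re-import,
    convex-hull expression-area and ellipse arc-length domain-width
    geometry, Gaussian fitting of the dorsal-ventral nuclear gradient, and
    the accompanying statistics (pooled t-test, one-way ANOVA with Tukey
    HSD, exact noncentral-t sample size, modified Akima series averaging).
    A synthetic-embryo generator with full ground truth makes every stage
    testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    png,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
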