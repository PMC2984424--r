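Package: oscseg
Title: Cellular-Oscillator Segmentation on a Uniformly Growing Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates sequential segment formation by cellular phase
    oscillators on a growing one-dimensional tissue. Implements a
    distributed-proliferation model in which the oscillation period is set
    by distance from the posterior end and cells freeze (segment) when
    their period reaches a critical value, alongside the classical
    posterior progress-zone variant in which the period grows with cell
    age. Provides closed-form oracles for the uniform-growth case,
    kymograph (space-time diagram) construction and export, segment-band
    detection and width analysis, a seeded generator of synthetic embryo
    nuclei point patterns with mitotic labels, and an exact-binomial plus
    permutation test for posterior proliferation-zone enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
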