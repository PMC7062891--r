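Package: tdbold
Title: Temporal-Difference Task Simulation and Synthetic BOLD Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a cued foraging task in which temporal-difference
    learning dissociates reward prediction errors at cues from mean reward
    rates during foraging, and provides the statistical machinery to test
    both signals in functional MRI data: canonical haemodynamic designs with
    parametric modulators, a synthetic 4-D BOLD phantom generator with AR(1)
    noise and between-subject variability, first-level GLM estimation with
    AR(1) prewhitening, second-level random-effects analysis, and
    permutation-based family-wise-error correction using maximal peak and
    cluster statistics, with whole-volume and region-of-interest variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
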