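Package: epiqsm
Title: Test-Retest Reliability of R2* and Susceptibility Mapping with
    Multi-Shot 3D EPI, by Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-echo T2*-weighted brain MRI acquisitions
    (conventional 3D gradient echo and multi-shot 3D echo-planar imaging
    with CAIPI undersampling) from digital phantoms with a susceptibility
    dipole forward model, shot-resolved physiological B0 fluctuation and
    translational motion, and bandwidth-scaled complex thermal noise.
    Reconstructs the data with and without shot-wise B0/motion correction,
    quantifies R2*, tissue frequency and magnetic susceptibility, and
    computes test-retest reliability statistics: normalized absolute
    difference maps and CDFs, inter-scan absolute differences, averaging
    curves, Monte Carlo thermal-noise floors and ROI consistency. Also
    provides the EPI distortion-correction evaluation (effective voxel
    size, correction accuracy) and T2*-decay point-spread-function
    blurring estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
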