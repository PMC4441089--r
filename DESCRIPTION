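Package: epimotion
Title: Motion Metrics and Artifact Simulation for Prospectively Corrected 3D EPI fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies head motion relative to k-space data acquisition in
    multi-shot 3D echo-planar imaging (EPI) fMRI and simulates the resulting
    image artifacts. Implements the total-speed, integrated-motion and
    k-space partition-weighted integrated-motion metrics computed from
    high-rate optical tracker logs, a partition-by-partition 3D EPI
    acquisition simulator with prospective motion correction (PMC) on or
    off, an image-quality pipeline (rigid realignment, temporal SNR with
    first-order detrending, motion-gated reference images, masked per-volume
    RMSE), a saturating-exponential artifact model relating RMSE to motion,
    and a factorial experiment runner that reproduces the design of
    camera-based PMC validation studies at desk scale using synthetic
    motion traces and digital phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    minpack.lm,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
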