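Package: waxstraj
Title: Wide-Angle X-Ray Scattering Reduction and Tissue Biomarker Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces wide-angle X-ray scattering (WAXS) detector frames of
    biological tissue to calibrated one-dimensional intensity-versus-q
    profiles, with pixel masking, Poisson error propagation and azimuthal
    integration; fits a composite model of Gaussian peaks on an inverse
    fourth-power amorphous background; computes the lipid/water peak-height
    structural biomarker; and assembles group-level disease trajectories with
    temporally matched controls. Includes a seeded synthetic-data generator
    that emulates a longitudinal mouse-prostate cohort (five groups, two
    prostate lobes, gridded measurement positions) with known ground truth,
    so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
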