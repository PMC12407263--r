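Package: lfaquant
Title: Quantitative Readout of Gold-Nanoparticle Lateral Flow Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantitative readout of colorimetric lateral
    flow immunoassay (LFA) strips. Provides a seeded synthetic strip
    generator with ground-truth labels; deterministic readout-zone
    detection, intensity-profile extraction and readout classification;
    a small fully connected neural network for per-pixel peak
    segmentation of intensity profiles; calibration-curve fitting with
    limit-of-detection estimation and hook-effect aware inversion for
    competitive three-line designs; clinical-range interpretation of a
    multiplexed biomarker panel (CEA, CA-125, CRP); and capillary
    microfluidics design equations (Laplace pressure, Hagen-Poiseuille
    flow, Washburn filling) for passive volume-control devices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
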