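Package: antgaze
Title: Gaze Analysis of Ant Learning-Walk Pirouettes Under Magnetic Field
    Alteration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for nest-directed gaze behavior of desert ants
    during learning-walk pirouettes under experimental alteration of the
    horizontal geomagnetic field component with a Helmholtz coil.  Converts
    per-frame mandible/thorax tracks into per-pirouette longest-stopping-phase
    gaze directions relative to the real and the fictive nest entrance,
    provides the circular-statistics battery (Rayleigh uniformity test, mean
    direction with Zar's 95% confidence interval, Mardia-Watson-Wheeler
    two-sample test, 10-degree binning), magnetic field vector algebra for
    coil-based field alterations, and a synthetic learning-walk generator
    with ground truth for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
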