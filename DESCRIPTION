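Package: froskd
Title: Apparent Dissociation Constants from Fluorescent Repressor Operator
    System Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures the in-vivo apparent dissociation constant (Kd) of a
    DNA-binding protein bound to a chromosomal operator array from
    fluorescence microscopy z-stacks, as in fluorescent repressor operator
    system (FROS) experiments. Provides a forward simulator of FROS
    z-stacks with full ground truth, per-cell chromosome-dot and
    ring-background quantification with autofluorescence correction and a
    bright-dot replication filter, intensity-to-concentration calibration
    against a saturated strain, Hill binding-curve fitting with standard
    errors, and closed-form kinetic models relating degradation and
    non-specific genomic-DNA competition to the apparent Kd.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
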