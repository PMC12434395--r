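Package: costar
Title: Cost of Resistance, Adaptive Therapy Simulation, and Resistant
    Subclone Tracking for Ovarian Cancer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the fitness cost of platinum resistance
    in high-grade serous ovarian cancer model systems and for exploiting it
    in silico. Provides logistic and two-population Lotka-Volterra
    competition growth models with nonlinear least-squares fitting,
    estimation of the fitness gap g = gs - gr from log sensitive:resistant
    ratio series with cross-seeding-ratio alignment, an in-silico trial
    engine comparing standard fixed-dose carboplatin with size-responsive
    adaptive dose modulation (Kaplan-Meier and log-rank endpoints), and
    longitudinal tracking of an emergent resistant subclone from
    segment-level copy-number profiles via a purity-corrected linear
    mixture model with integer subclone alterations and a subsampling
    bootstrap confidence interval. A synthetic-data module generates all
    study-shaped inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    survival,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
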