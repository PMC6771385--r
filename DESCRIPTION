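Package: pauseflux
Title: Kinetic Modeling and Quantification of RNA Polymerase II
    Promoter-Proximal Pausing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-compartment kinetic model of RNA polymerase II
    promoter-proximal pausing: ordinary differential equation dynamics for
    Pol II density in the pause region and gene body, closed-form steady
    states and pause index, exact parameter-sensitivity algebra with the
    effect-ratio identity, and a sum-of-exponentials waveform for rendering
    steady states as smooth pause-peak/gene-body profiles. Includes a
    synthetic PRO-seq-like track generator (strand-specific per-base counts
    under Poisson noise, bedGraph/BED output), pause and gene-body density
    quantification with composite profiles and between-condition fold
    changes, mechanism classification mapping density changes onto rate
    constants, and one-phase exponential decay fitting for degradation
    time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
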