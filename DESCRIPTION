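Package: parbslide
Title: Simulation and Analysis of ParB Sliding-Clamp Dynamics on DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-molecule studies of the bacterial partition
    protein ParB. Provides coordinate maps of parS-containing DNA substrates,
    a stochastic simulator of CTP-gated ParB loading at parS and subsequent
    one-dimensional sliding-clamp diffusion with protein roadblocks and
    photobleaching, a confocal/kymograph image synthesizer with Gaussian
    point-spread-function blur and Poisson shot noise, kymograph particle
    tracking with mean-squared-displacement diffusion estimation,
    tethered-particle-motion analysis with drift-suppressed windowed RMS
    excursions and condensation detection, and worm-like-chain
    force-extension fitting with contour-length quality filtering for
    magnetic-tweezers condensation assays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
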