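Package: mousedyn
Title: Movement Dynamics of Unconstrained Mouse-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing continuous, unsegmented 2-D cursor streams.
    Trajectories are embedded in the complex plane (z = x + iy), resampled to
    a uniform grid, and Fourier transformed; a reference subspace fitted by
    singular value decomposition of a cohort's spectra yields the projection
    diagnostic eta, which measures how well a new trace fits the reference
    cohort's spectral structure. A complex-valued generalization of detrended
    fluctuation analysis estimates the scaling exponent alpha and its Hurst
    interpretation. Includes synthetic-data generators (fractional Gaussian
    noise by circulant embedding, planted spectral cohorts, and an agent-based
    Whac-A-Mole game simulator) and an end-to-end study pipeline with group
    comparison and regression reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
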