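Package: nifs
Title: Nanowaveguide-Illuminated Fluorescence Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for fluorescence correlation
    spectroscopy (FCS) under deep-subwavelength near-field illumination from a
    nanowire waveguide (NIFS).  Provides analytic illumination profiles
    (Gaussian ellipsoid, exponentially decaying near field, annular Gaussian),
    a Brownian-dynamics Monte Carlo photon-count simulator with periodic and
    reflecting boundaries, direct autocorrelation estimation on
    quasi-logarithmic lag grids, closed-form autocorrelation models for
    conventional FCS, 3D NIFS and membrane (2D) NIFS together with a numeric
    correlation-integral oracle, and weighted nonlinear least-squares fitting
    that recovers diffusion times and effective illumination volumes or areas.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
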