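Package: xpcsdyn
Title: Speckle Correlation Analysis of Beam-Stimulated Nanoscale Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for X-ray photon correlation spectroscopy (XPCS) of slow
    nanoscale dynamics in hydrated protein powders and related soft granular
    materials. Computes intensity autocorrelation functions g2 and two-time
    correlation matrices per momentum-transfer bin, fits
    Kohlrausch-Williams-Watts (compressed/stretched exponential) decays,
    beam-flux coupling (1/tau = 1/tau0 + a*F) and Arrhenius temperature
    dependence, and quantifies dynamical heterogeneity through the
    normalized variance chi_T of the two-time correlation. Includes two
    independent synthetic speckle generators (a Levy-stable ballistic
    scatterer model and a circulant-embedding Gaussian-field oracle) with
    known ground truths, detector geometry/Q-mapping, masking, azimuthal
    averaging, plain-text frame-stack I/O, and end-to-end flux and
    temperature-scan pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    data.table
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
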