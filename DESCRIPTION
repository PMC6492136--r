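Package: octmc
Title: Monte Carlo Simulation of Frequency-Domain Optical Coherence Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates frequency-domain optical coherence tomography (FDOCT)
    A-scans of multilayered tissue phantoms by Monte Carlo photon transport.
    The incident light is a focusing Gaussian beam: ballistic photon packets
    follow trajectories normal to the wavefront of the beam until their first
    scattering event, after which they propagate as in conventional layered
    Monte Carlo codes. Backscattered packets are detected by back-propagating
    their exit rays through the 4F sample-arm optics to the plane conjugate to
    their scattering depth and modulating their weight by the reference-beam
    intensity there. Wavenumber-resolved interference spectra are accumulated
    from the detected packets and reconstructed into depth profiles by inverse
    Fourier transform. The package also provides the analytical
    extended-Huygens-Fresnel (EHF) forward model of the mean-squared heterodyne
    signal, genetic-algorithm fitting of tissue optical properties (scattering
    coefficient, anisotropy factor, backscattering probability) to simulated
    A-scans, and a linear-perturbation sensitivity analysis of the inverse
    problem.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
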