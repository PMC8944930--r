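Package: homolink
Title: Random-Link Rouse Models and Trajectory Statistics for Meiotic
    Homolog Pairing Dynamics
Version: 0.1.0
Authors@R:
    person("homolink", "developers", email = "homolink@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing two-locus live-imaging trajectories of
    homologous chromosomal loci during meiotic prophase, together with the
    polymer-physics model that explains them: viscoelastic Rouse chains
    confined to the nucleus, Rabl centromere tethering, and a Poisson number
    of random interhomolog linkages.  Provides an exact-covariance synthetic
    trajectory generator emulating 25-minute two-colour movies, colocalization
    and dwell-time statistics, mean-square-change-in-distance (MSCD) curves
    with power-law/plateau fits, first-passage dwell-time models, and the full
    calibration chain recovering Kuhn length, Rabl exit rate, confinement
    radius, mean linkage number and subdiffusion coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
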