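Package: redoxkin
Title: Kinetic Analysis of Protein Disulfide-Bond Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the reduction of protein disulfide bonds from
    spectroscopic time courses. Implements a four-reaction mass-action redox
    mechanism (second-order reduction by TCEP or DTT, reoxidation by dissolved
    oxygen, first-order precipitation, zero-order oxygen ingress), stiff ODE
    simulation, Levenberg-Marquardt estimation of rate constants with
    Student-t confidence intervals, closed-form second-order half-lives,
    Arrhenius activation-energy analysis, an exponential helix-length
    half-life regression, conversion of circular-dichroism ellipticity and
    NMR integrals to concentrations, CPMG transverse relaxation rates,
    structure-derived steric descriptors, and a convex two-component
    factorization of thermal far-UV CD spectrum ensembles. A synthetic-data
    generator with known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
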