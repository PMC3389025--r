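Package: cellsamp
Title: Declarative Parameter Uncertainty for CellML Models with Sampling
    Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("cellsamp", "maintainers", email = "cellsamp@example.org",
           role = c("aut", "cre"))
Description: Reads and writes CellML 1.0/1.1 models whose mathematics is
    Content MathML, including three csymbol operators
    (uncertainParameterWithDistribution, distributionFromDensity,
    distributionFromRealisations) that attach probability distributions to
    model parameters either as symbolic probability density functions or as
    vectors of realisations.  Draws parameter values from symbolic densities
    by numerical inversion of the cumulative distribution function (tangent
    change of variable plus adaptive quadrature) and from realisation
    vectors by uniform index selection, integrates the resulting ODE
    initial-value problems with an adaptive Runge-Kutta method, and executes
    SED-ML experiment descriptions including a SamplingSensitivityAnalysis
    extension for Monte Carlo sensitivity analysis.  Ships a fixture
    generator that rebuilds the projectile example model and its two-spring
    mixture posterior (Metropolis-within-Gibbs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
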