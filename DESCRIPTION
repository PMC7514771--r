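Package: detomo
Title: Diffusion-Assisted Two-Level MCMC for Inverse Radiative Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian reconstruction of a tissue's scattering coefficient from
    boundary light measurements. Provides a discrete-ordinates upwind solver for
    the scaled radiative transfer equation (RTE) in a slab and on the unit
    square, a finite-difference solver for its diffusion-equation (DE) limit,
    forward measurement maps built from the albedo operator and the
    Dirichlet-to-Neumann map, Gaussian-likelihood posteriors over parametric
    media, one-level random-walk Metropolis-Hastings, and a delayed-acceptance
    two-level sampler in which the cheap DE posterior pre-screens proposals
    before the expensive RTE posterior is evaluated. Includes kernel density
    estimation on parameter grids, Hellinger and Kullback-Leibler distances
    between sampled posteriors, and a cost model for the two-level scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
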