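Package: latentord
Title: Bayesian Latent Factor Models for Unconstrained Ordination with
    Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Model-based unconstrained ordination of site-by-species
    community matrices using Bayesian latent factor models for
    presence-absence (probit), count (Poisson and negative binomial) and
    ordinal cover-class (cumulative probit) responses.  Provides Gibbs and
    Metropolis-within-Gibbs samplers with identifiability constraints on
    the factor loadings, highest posterior density (HPD) interval and
    region summaries for the latent factors, anchored relative
    ordinations, uncertainty-aware ordination graphics, and a
    simulation-based design tool that estimates the expected HPD width of
    the latent factors for a planned study as a function of the numbers of
    sites and species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    MASS,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan
Config/testthat/edition: 3
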