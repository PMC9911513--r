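Package: abcpred
Title: Posterior Predictive Inference for Intractable Models via
    Approximate Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-free (simulator-based) approximation of the posterior
    predictive distribution using approximate Bayesian computation (ABC).
    Implements three complementary approximations: ABC-F (standard ABC for the
    parameters followed by direct conditional-predictive simulation), ABC-P
    (joint simulation of observed and future data with acceptance on summarized
    observed data) and ABC-L (joint ABC inference of parameters and latent
    variables followed by latent-conditional prediction), together with
    rejection, self-normalized importance sampling and Markov chain Monte Carlo
    samplers for the augmented ABC targets.  Bundles four simulator models used
    to validate the approximations: a Gaussian AR(1) Markov chain with
    closed-form ABC posterior and predictive oracles, a Gaussian linear
    state-space model with exact sufficiency identities, the M/G/1 queue, and
    the stochastic Lotka-Volterra Markov jump process simulated exactly with
    the Gillespie algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
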