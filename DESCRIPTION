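Package: boaspom
Title: Seed-Bank Stochastic Patch Occupancy Models and Metapopulation
    Extinction Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian inference for the Best Occupancy
    Achievable (BOA) process, a stochastic patch occupancy model with a
    soil seed bank for plant metapopulations on a line of patches (such
    as street tree bases), and for its noisy variant that buffers
    observation errors and weak external colonisation.  Provides the
    exact hidden-Markov-model likelihood of yearly presence/absence
    records, Metropolis-within-Gibbs posterior sampling of the patch
    extinction probability, initial seed occupancy, maximal dormancy
    duration and noise intensity (with missing-observation
    augmentation), Monte-Carlo estimation of the critical patch
    extinction threshold by bisection, and the GER, MaxGER, LER and SMD
    extinction-risk metrics, together with a simulation-study harness
    assessing their robustness to false positives, false negatives and
    external colonisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
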