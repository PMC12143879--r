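Package: dualpop
Title: Directed Functional Influence Between Two Simultaneously Recorded
    Neural Populations
Version: 0.1.0
Authors@R:
    person("Dualpop", "Developers", email = "dualpop@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying asymmetric functional influence between
    two simultaneously recorded motor cortical populations. Provides a
    synthetic session generator with known ground truth (shared latents at
    configurable temporal delays, Poisson spiking, reach-locked EMG bursts,
    optogenetic-style inactivation trials); EMG conditioning and
    double-threshold reach-onset detection; trial exclusion and post-sorting
    unit curation; perturbation-effect quantification with chance-level
    correction and a modified stimulus-associated spike latency test;
    population alignment by canonical correlation analysis and partial least
    squares with lag scans and shifted-time controls; a two-population
    delayed-latent factor model fit by expectation-maximization with
    per-latent continuous delays; pairwise directed predictivity by transfer
    entropy, point-process Granger causality, and convergent cross mapping
    with circular-permutation nulls; and a Dale-constrained dual-population
    recurrent rate network trained against condition-specific targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
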