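Package: psmarch
Title: Projective-Simulation Agents for Density-Dependent Collective Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates groups of two-layer projective-simulation (PS)
    reinforcement-learning agents marching on a one-dimensional periodic
    arena, the minimal laboratory setting in which locust nymphs show
    density-dependent alignment. Agents perceive the net flow of
    conspecifics within a sensory range, decide stochastically whether to
    turn, and are rewarded for moving with the local majority; their
    episodic memory (h-values) is reinforced and damped by a forgetting
    rate. The package provides the fixed-disposition (self-propelled
    particle) limit, full learning dynamics, Monte-Carlo estimation of the
    one-step transition kernel of the group alignment parameter, mean-field
    and empirical Kramers-Moyal drift/diffusion coefficients of the
    associated Fokker-Planck equation, fixed-point stability analysis, and
    summaries of regimes, directional switching and learning curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
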