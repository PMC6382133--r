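# Shared test fixtures: tiny swarms built in code.

# A swarm with prescribed positions/headings and a shared fixed policy.
fixture_swarm <- function(position, heading, d = 0, W = 80L, r = 5L) {
  cfg <- world_config(W = W, r = r, N = length(position))
  swarm_state(position, heading, make_fixed_disposition(d), cfg)
}

# A hand-built transition-kernel object (for exercising km_from_kernel
# on exactly known kernels).
fixture_kernel <- function(P, N, counts = rep(1000L, N + 1L)) {
  structure(list(grid = z_grid(N), P = P, counts = counts,
                 cfg = world_config(N = N), policy = make_neutral_memory()),
            class = "transition_kernel")
}

# Drift/diffusion curves with prescribed values (for root-finding tests).
dd_curves_for_test <- function(z, F, D = rep(0, length(z))) {
  psmarch:::dd_curves(z, F, D, method = "test")
}

# Mean labels over seeds for regime runs.
run_labels <- function(N, seeds, steps = 2000L, d = 30, mode = "fixed",
                       gamma = NULL, window = NULL) {
  vapply(seeds, function(s) {
    args <- list(N = N, mode = mode, steps = steps, seed = s)
    if (mode == "fixed") args$d <- d else args$gamma <- gamma
    rec <- run_simulation(do.call(sim_config, args))
    switching_statistics(rec, window = window)$label
  }, character(1))
}
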