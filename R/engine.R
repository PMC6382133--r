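#' Simulation configuration
#'
#' Bundles the world, agent and run parameters of one simulation. In
#' `fixed` mode agents share the pre-programmed disposition of
#' decisiveness `d` (and optional inertia) and never update their
#' memories; in `learning` mode every agent starts from the neutral
#' memory and applies the reinforcement-with-forgetting rule with rate
#' `gamma` each turn.
#'
#' @param N population size.
#' @param mode `"fixed"` or `"learning"`.
#' @param W world size in blocks.
#' @param r sensory range in blocks.
#' @param d decisiveness (fixed mode only).
#' @param gamma forgetting rate in \[0,1\] (learning mode only).
#' @param inertia non-negative inertia added to `h(0, +1)`.
#' @param steps number of sweeps to run.
#' @param seed RNG seed (integer) or `NULL` to use the current stream.
#' @param record `"z"` (alignment series only), `"turns"` (plus per-turn
#'   percept/action/reward logs) or `"memory"` (plus h-matrix snapshots).
#' @param snapshot_every snapshot interval in sweeps (with
#'   `record = "memory"`).
#' @param move `"per_sweep"`: all agents advance one block after the last
#'   turn of the sweep; `"per_turn"`: each agent advances right after its
#'   own turn.
#' @param reward_ties reward an exact tie among neighbours?
#' @return a `sim_config` object.
#' @export
sim_config <- function(N, mode = c("fixed", "learning"), W = 80L, r = 5L,
                       d = NULL, gamma = NULL, inertia = 0,
                       steps = 1000L, seed = NULL,
                       record = c("z", "turns", "memory"),
                       snapshot_every = 50L,
                       move = c("per_sweep", "per_turn"),
                       reward_ties = FALSE) {
  mode <- match.arg(mode)
  record <- match.arg(record)
  move <- match.arg(move)
  cfg <- world_config(W = W, r = r, N = N)
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("`steps` must be at least 1")
  if (mode == "fixed") {
    if (!is.null(gamma))
      stop("`gamma` applies to learning agents only; fixed mode never updates memory")
    if (is.null(d)) stop("fixed mode requires a decisiveness `d`")
    if (d < 0) stop("`d` must be non-negative")
  } else {
    if (!is.null(d))
      stop("`d` parametrises the fixed disposition; learning agents develop their own")
    if (is.null(gamma)) gamma <- 0.002
    if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]")
  }
  if (inertia < 0) stop("`inertia` must be non-negative")
  structure(list(world = cfg, mode = mode, d = d, gamma = gamma,
                 inertia = inertia, steps = steps, seed = seed,
                 record = record, snapshot_every = as.integer(snapshot_every),
                 move = move, reward_ties = isTRUE(reward_ties)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> N = %d, W = %d, r = %d (B = %g), mode = %s\n",
              x$world$N, x$world$W, x$world$r, x$world$B, x$mode))
  if (x$mode == "fixed") cat(sprintf("  d = %g, inertia = %g\n", x$d, x$inertia))
  else cat(sprintf("  gamma = %g, inertia = %g\n", x$gamma, x$inertia))
  cat(sprintf("  steps = %d, seed = %s, record = %s, move = %s\n",
              x$steps, if (is.null(x$seed)) "<current RNG>" else x$seed,
              x$record, x$move))
  invisible(x)
}

#' Named parameter presets
#'
#' The standard study conditions: world `W = 80`, sensory range `r = 5`
#' (`B = 8` neighbourhoods), populations 10/40/70, decisiveness 30 for
#' fixed agents and forgetting 0.002 (or 0) for learning agents.
#'
#' @param name one of `"fig2a"`, `"fig2b"`, `"fig2c"` (fixed mode,
#'   d = 30, N = 10/40/70), `"fig4a"`, `"fig4b"`, `"fig4c"` (learning,
#'   gamma = 0.002, N = 10/40/70), `"fig7"` (learning, gamma = 0, N = 10).
#' @param ... overrides passed on to [sim_config()] (e.g. `steps`, `seed`).
#' @return a [sim_config()].
#' @export
preset_config <- function(name, ...) {
  presets <- list(
    fig2a = list(N = 10L, mode = "fixed", d = 30),
    fig2b = list(N = 40L, mode = "fixed", d = 30),
    fig2c = list(N = 70L, mode = "fixed", d = 30),
    fig4a = list(N = 10L, mode = "learning", gamma = 0.002),
    fig4b = list(N = 40L, mode = "learning", gamma = 0.002),
    fig4c = list(N = 70L, mode = "learning", gamma = 0.002),
    fig7  = list(N = 10L, mode = "learning", gamma = 0))
  if (!name %in% names(presets))
    stop("unknown preset; available: ", paste(names(presets), collapse = ", "))
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(sim_config, args)
}

# Flatten memory to the 10 x k matrix layout the C++ core uses.
memory_to_cols <- function(memory) {
  if (inherits(memory, "hmatrix")) matrix(as.numeric(memory), 10, 1)
  else vapply(memory, function(m) as.numeric(m), numeric(10))
}

cols_to_memory <- function(mat, shared) {
  if (shared) hmatrix(matrix(mat[, 1], 5, 2))
  else lapply(seq_len(ncol(mat)), function(i) hmatrix(matrix(mat[, i], 5, 2)))
}

#' Run a simulation
#'
#' Draws the initial swarm (uniform positions and headings) from the
#' seeded RNG and applies `steps` asynchronous sweeps using the compiled
#' core. The alignment parameter is recorded after every completed sweep;
#' index 0 of the series is the initial random state. Re-running with the
#' same configuration (and seed) is bit-identical.
#'
#' @param config a [sim_config()].
#' @return a `ps_trajectory` object: list with elements `t` (0..steps),
#'   `z`, the final [swarm_state()] (`final`), optional `logs` data frame
#'   (`t`, `agent_id`, `percept`, `action`, `reward`), optional memory
#'   `snapshots` (5 x 2 x N arrays) with `snapshot_t`, and the `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  cfg <- config$world
  learning <- config$mode == "learning"
  memory <- if (learning) {
    h0 <- if (config$inertia > 0)
      make_fixed_disposition(0, config$inertia) else make_neutral_memory()
    rep(list(h0), cfg$N)
  } else {
    make_fixed_disposition(config$d, config$inertia)
  }
  swarm <- init_swarm(cfg, memory)
  hcols <- memory_to_cols(swarm$memory)
  snap_every <- if (config$record == "memory") config$snapshot_every else 0L
  res <- cpp_run_sweeps(swarm$position, swarm$heading, hcols,
                        cfg$W, cfg$r, learning,
                        if (learning) config$gamma else 0,
                        config$steps, config$reward_ties,
                        config$move == "per_turn",
                        snap_every, config$record == "turns")
  final <- swarm_state(res$position, res$heading,
                       cols_to_memory(res$hmem, !learning), cfg,
                       t = config$steps)
  out <- list(t = 0:config$steps, z = as.numeric(res$z), final = final,
              config = config)
  if (config$record == "turns") {
    logs <- as.data.frame(res$logs)
    names(logs) <- c("t", "agent_id", "percept", "action", "reward")
    out$logs <- logs
  }
  if (config$record == "memory") {
    nsnap <- length(res$snapshot_t)
    out$snapshots <- lapply(seq_len(nsnap), function(k) {
      block <- res$snapshots[((k - 1) * 10 * ncol(hcols) + 1):(k * 10 * ncol(hcols))]
      array(block, dim = c(5L, 2L, ncol(hcols)),
            dimnames = list(s = as.character(PERCEPTS),
                            a = as.character(ACTIONS), NULL))
    })
    out$snapshot_t <- res$snapshot_t
  }
  class(out) <- "ps_trajectory"
  out
}

#' @export
print.ps_trajectory <- function(x, ...) {
  if (is.null(x$config))
    cat(sprintf("<ps_trajectory> %d sweeps\n", length(x$z) - 1L))
  else
    cat(sprintf("<ps_trajectory> %d sweeps, N = %d, mode = %s\n",
                x$config$steps, x$config$world$N, x$config$mode))
  cat(sprintf("  final z = %.3f; mean |z| over last half = %.3f\n",
              tail(x$z, 1), mean(abs(tail(x$z, ceiling(length(x$z) / 2))))))
  invisible(x)
}

#' Write / read a trajectory
#'
#' The alignment series goes to a two-column CSV (`t,z`); per-turn logs,
#' when present, go to a sibling file `<path>.logs.csv`
#' (`t,agent_id,percept,action,reward`). `read_trajectory` restores both
#' losslessly (configuration and memory snapshots are not serialised).
#'
#' @param record a `ps_trajectory` (or anything with `t` and `z`).
#' @param path CSV path for the `t,z` series.
#' @return `read_trajectory` returns a `ps_trajectory` (without config).
#' @export
write_trajectory <- function(record, path) {
  write.csv(data.frame(t = record$t, z = record$z), path, row.names = FALSE)
  if (!is.null(record$logs))
    write.csv(record$logs, logs_path(path), row.names = FALSE)
  invisible(path)
}

logs_path <- function(path) paste0(path, ".logs.csv")

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  if (!identical(names(df), c("t", "z")))
    stop("not a trajectory CSV: expected header `t,z`")
  out <- list(t = df$t, z = df$z)
  if (file.exists(logs_path(path))) {
    logs <- read.csv(logs_path(path))
    want <- c("t", "agent_id", "percept", "action", "reward")
    if (!identical(names(logs), want))
      stop("malformed log file: expected header ", paste(want, collapse = ","))
    out$logs <- logs
  }
  class(out) <- "ps_trajectory"
  out
}
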