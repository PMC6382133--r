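#' World configuration
#'
#' The arena is a one-dimensional ring of `W` discrete blocks with periodic
#' boundaries. Agents move one block per time-step and sense all others
#' within ring distance `r`, which partitions the world into
#' `B = W / (2 r)` non-overlapping neighbourhoods; the effective density
#' `N / B` is the control parameter of the order-disorder transition.
#'
#' @param W world size in blocks (positive integer).
#' @param r sensory range in blocks (positive integer, `2 r < W`).
#' @param N population size (positive integer).
#' @return a `world_config` list with fields `W`, `r`, `N` and derived `B`.
#' @export
world_config <- function(W = 80L, r = 5L, N) {
  W <- as.integer(W); r <- as.integer(r); N <- as.integer(N)
  if (is.na(W) || W <= 0L) stop("`W` must be a positive integer")
  if (is.na(r) || r <= 0L) stop("`r` must be a positive integer")
  if (2L * r >= W) stop("sensory range must satisfy 2*r < W")
  if (is.na(N) || N <= 0L) stop("`N` must be a positive integer")
  structure(list(W = W, r = r, N = N, B = W / (2 * r)),
            class = "world_config")
}

#' Ring distance between two blocks
#'
#' Shortest distance on the periodic arena, in blocks.
#'
#' @param x1,x2 block positions in `[0, W)`.
#' @param W world size.
#' @return integer distance in `[0, W/2]`.
#' @export
ring_distance <- function(x1, x2, W) {
  if (any(x1 < 0 | x1 >= W) || any(x2 < 0 | x2 >= W))
    stop("positions must lie in [0, W)")
  d <- abs(x1 - x2)
  pmin(d, W - d)
}

#' Swarm state
#'
#' Positions and headings of all `N` agents at one time-step, plus their
#' memories. The agent order is fixed for the whole run: agents deliberate
#' one after another in index order, so the order is part of the dynamics.
#'
#' @param position integer vector of block positions in `[0, W)`.
#' @param heading integer vector of headings, each -1 or +1.
#' @param memory a single [hmatrix()] shared by all agents (fixed mode) or
#'   a list of per-agent h-matrices (learning mode).
#' @param cfg a [world_config()].
#' @param t time-step counter (number of completed sweeps).
#' @return a `swarm_state` object.
#' @export
swarm_state <- function(position, heading, memory, cfg, t = 0L) {
  position <- as.integer(position); heading <- as.integer(heading)
  if (length(position) != cfg$N || length(heading) != cfg$N)
    stop("position and heading must have length N")
  if (any(position < 0L | position >= cfg$W))
    stop("positions must lie in [0, W)")
  if (!all(heading %in% c(-1L, 1L)))
    stop("headings must be -1 or +1")
  if (is.list(memory) && !inherits(memory, "hmatrix") &&
      length(memory) != cfg$N)
    stop("per-agent memory list must have length N")
  structure(list(position = position, heading = heading,
                 memory = memory, cfg = cfg, t = as.integer(t)),
            class = "swarm_state")
}

#' @export
print.swarm_state <- function(x, ...) {
  cat(sprintf("<swarm_state> N = %d on a ring of W = %d (t = %d), z = %.3f\n",
              x$cfg$N, x$cfg$W, x$t, alignment(x)))
  invisible(x)
}

#' Random initial swarm
#'
#' Positions i.i.d. uniform over blocks, headings i.i.d. uniform on
#' \{-1, +1\}, drawn from the current RNG stream.
#'
#' @param cfg a [world_config()].
#' @param memory shared [hmatrix()] or list of per-agent memories.
#' @return a [swarm_state()].
#' @export
init_swarm <- function(cfg, memory = make_neutral_memory()) {
  position <- as.integer(floor(runif(cfg$N) * cfg$W))
  heading <- ifelse(runif(cfg$N) < 0.5, -1L, 1L)
  swarm_state(position, heading, memory, cfg)
}

#' Percept of a focal agent
#'
#' The net flow of conspecifics within sensory range relative to the focal
#' agent: the number of neighbours (ring distance at most `r`, excluding
#' the focal itself, co-located agents included) heading the same way minus
#' those heading the opposite way, clipped to \{-2,...,+2\}.
#'
#' @param i index of the focal agent.
#' @param swarm a [swarm_state()].
#' @return integer percept in -2..+2.
#' @export
compute_percept <- function(i, swarm) {
  nb <- neighbour_idx(i, swarm)
  same <- sum(swarm$heading[nb] == swarm$heading[i])
  opp <- length(nb) - same
  max(-2L, min(2L, same - opp))
}

neighbour_idx <- function(i, swarm) {
  d <- ring_distance(swarm$position[i], swarm$position, swarm$cfg$W)
  which(d <= swarm$cfg$r & seq_along(d) != i)
}

#' Reward of a focal agent after acting
#'
#' `R = 1` if, at the end of its turn, the focal agent moves in the same
#' direction as the strict majority of its neighbours within range;
#' `R = 0` otherwise. By default a tie or an empty neighbourhood gives no
#' reward ("majority" read strictly); `reward_ties = TRUE` rewards ties.
#'
#' @param i index of the focal agent (heading already reflects its action).
#' @param swarm a [swarm_state()].
#' @param reward_ties logical; reward exact ties?
#' @return 0L or 1L.
#' @export
compute_reward <- function(i, swarm, reward_ties = FALSE) {
  nb <- neighbour_idx(i, swarm)
  if (length(nb) == 0L) return(0L)
  same <- sum(swarm$heading[nb] == swarm$heading[i])
  opp <- length(nb) - same
  if (same > opp || (reward_ties && same == opp)) 1L else 0L
}

#' Group alignment parameter
#'
#' `z = (1/N) sum_i sigma_i`, the order parameter of the swarm:
#' -1 and +1 are fully ordered marching in either direction, 0 is
#' completely disordered. `z` lives on the grid `(2m - N)/N`, m = 0..N.
#'
#' @param swarm a [swarm_state()] (or an integer heading vector).
#' @return numeric in \[-1, 1\].
#' @export
alignment <- function(swarm) {
  h <- if (inherits(swarm, "swarm_state")) swarm$heading else swarm
  mean(h)
}

#' One asynchronous time-step (reference implementation)
#'
#' Performs one full sweep in pure R: every agent, in fixed index order,
#' perceives the net flow around it, deliberates (one uniform draw),
#' possibly turns, and is rewarded against its neighbours' current
#' headings — agents earlier in the order have already acted, later ones
#' have not. In learning mode the reinforcement-with-forgetting update is
#' applied to the acting agent's memory. After the N-th turn all agents
#' advance one block along their heading (default), or each agent steps
#' immediately after its own turn when `move = "per_turn"`.
#'
#' This is the readable reference for the compiled core used by
#' [run_simulation()]; both consume the RNG stream identically (one
#' uniform per turn), so their trajectories agree exactly.
#'
#' @param swarm a [swarm_state()].
#' @param learning logical; apply memory updates?
#' @param gamma forgetting rate (learning mode).
#' @param reward_ties logical, see [compute_reward()].
#' @param move `"per_sweep"` (default) or `"per_turn"`.
#' @return the successor [swarm_state()] with `t` incremented.
#' @export
sweep_swarm <- function(swarm, learning = FALSE, gamma = 0,
                        reward_ties = FALSE,
                        move = c("per_sweep", "per_turn")) {
  move <- match.arg(move)
  cfg <- swarm$cfg
  shared <- inherits(swarm$memory, "hmatrix")
  for (i in seq_len(cfg$N)) {
    s <- compute_percept(i, swarm)
    h <- if (shared) swarm$memory else swarm$memory[[i]]
    p <- action_probabilities(h, s)
    a <- sample_action(p)
    if (a == -1L) swarm$heading[i] <- -swarm$heading[i]
    R <- compute_reward(i, swarm, reward_ties)
    if (learning) {
      upd <- update_memory(h, s, a, R, gamma)
      if (shared) swarm$memory <- upd else swarm$memory[[i]] <- upd
    }
    if (move == "per_turn")
      swarm$position[i] <- (swarm$position[i] + swarm$heading[i]) %% cfg$W
  }
  if (move == "per_sweep")
    swarm$position <- (swarm$position + swarm$heading) %% cfg$W
  swarm$t <- swarm$t + 1L
  swarm
}
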