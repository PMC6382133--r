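#' @useDynLib psmarch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif var sd median dbinom setNames quantile
#' @importFrom utils read.csv write.csv head tail
NULL

PERCEPTS <- c(-2L, -1L, 0L, 1L, 2L)
ACTIONS  <- c(-1L, 1L)  # -1 = turn around, +1 = continue

#' Construct an h-matrix
#'
#' The episodic memory of a two-layer projective-simulation agent is a 5 x 2
#' table of h-values, one per percept-action edge. Percepts index the net
#' flow of neighbours relative to the agent, clipped to \{-2,...,+2\};
#' actions are turning around (-1) or continuing (+1). All h-values are
#' at least 1: the update rule damps them towards 1, never below.
#'
#' @param h numeric 5 x 2 matrix of h-values (rows: percepts -2..+2,
#'   columns: actions -1, +1). Defaults to the neutral memory of all ones.
#' @return an object of class `hmatrix`.
#' @seealso [make_neutral_memory()], [make_fixed_disposition()]
#' @export
hmatrix <- function(h = matrix(1, 5, 2)) {
  h <- as.matrix(h)
  if (!identical(dim(h), c(5L, 2L)))
    stop("an h-matrix must be 5 x 2 (percepts -2..+2 by actions -1,+1)")
  if (!is.numeric(h) || anyNA(h))
    stop("h-values must be numeric and non-missing")
  if (any(h < 1))
    stop("h-values must all be >= 1")
  dimnames(h) <- list(s = as.character(PERCEPTS), a = as.character(ACTIONS))
  class(h) <- c("hmatrix", "matrix")
  h
}

#' @export
print.hmatrix <- function(x, ...) {
  cat("<hmatrix> h-values (rows: percept s; columns: action a)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Neutral memory
#'
#' All h-values equal to 1, so every percept maps to both actions with
#' probability one half. This is the initial condition for learning agents.
#'
#' @return an [hmatrix()] of ones.
#' @export
make_neutral_memory <- function() hmatrix()

#' Fixed behavioural disposition
#'
#' Pre-programmed h-matrix that reduces the agent to a self-propelled
#' particle: a single decisiveness parameter `d` controls how strongly the
#' agent keeps its direction when aligned with the local net flow
#' (percepts +1, +2) and turns around when opposed (percepts -1, -2):
#' `h(+2,+1) = h(-2,-1) = 1 + d`, `h(+1,+1) = h(-1,-1) = 1 + d/2`, all
#' other entries 1. An optional inertia `iota` raises `h(0,+1)` to
#' `1 + iota`, making continuation the preferred response to a zero net
#' flow (energetically the cheaper action for a real animal).
#'
#' @param d decisiveness, a non-negative number.
#' @param iota inertia, a non-negative number (default 0).
#' @return an [hmatrix()].
#' @export
make_fixed_disposition <- function(d, iota = 0) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("decisiveness `d` must be a single non-negative number")
  if (!is.numeric(iota) || length(iota) != 1L || is.na(iota) || iota < 0)
    stop("inertia `iota` must be a single non-negative number")
  h <- matrix(1, 5, 2)
  h[p_idx(+2L), a_idx(+1L)] <- 1 + d
  h[p_idx(-2L), a_idx(-1L)] <- 1 + d
  h[p_idx(+1L), a_idx(+1L)] <- 1 + d / 2
  h[p_idx(-1L), a_idx(-1L)] <- 1 + d / 2
  h[p_idx(0L),  a_idx(+1L)] <- 1 + iota
  hmatrix(h)
}

# row/column index helpers: percept s in {-2..2} -> 1..5, action in {-1,1} -> 1..2
p_idx <- function(s) {
  s <- as.integer(s)
  if (any(!s %in% PERCEPTS)) stop("unknown percept index; must be in -2..+2")
  s + 3L
}

a_idx <- function(a) {
  a <- as.integer(a)
  if (any(!a %in% ACTIONS)) stop("unknown action; must be -1 or +1")
  (a + 1L) / 2L + 1L
}

#' Action probabilities for a percept
#'
#' Normalises the h-values of the row belonging to percept `s`:
#' `P(a|s) = h(s,a) / sum_a' h(s,a')`.
#'
#' @param h an [hmatrix()] (any 5 x 2 non-negative table is accepted, so
#'   averaged policies can be queried too).
#' @param s percept in -2..+2.
#' @return named numeric vector `c("-1" = P(turn), "1" = P(continue))`.
#' @export
action_probabilities <- function(h, s) {
  row <- h[p_idx(s), ]
  p <- row / sum(row)
  setNames(as.numeric(p), as.character(ACTIONS))
}

#' Sample an action
#'
#' Draws an action from a probability pair over \{-1, +1\} using the
#' current R random number stream. The draw consumes exactly one uniform
#' variate: the action is -1 (turn) when `u < p[1]`, else +1; this is the
#' convention used throughout the simulation core, so seeded runs are
#' reproducible bit-for-bit.
#'
#' @param p probability pair as returned by [action_probabilities()]
#'   (first element: turn, second: continue).
#' @return -1L or +1L.
#' @export
sample_action <- function(p) {
  if (length(p) != 2L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("`p` must be two non-negative probabilities summing to 1")
  if (runif(1) < p[[1L]]) -1L else 1L
}

#' Reinforcement-with-forgetting memory update
#'
#' Applies one interaction's update to the whole memory: every h-value is
#' damped towards 1 by the forgetting factor, `h' - 1 = (1 - gamma)(h - 1)`,
#' and the reward `R` is then added on the percept-action edge that was
#' used in this turn's deliberation. With `gamma = 0` the agent never
#' forgets and rewarded h-values grow without bound; with `gamma = 1` it
#' forgets immediately and cannot learn.
#'
#' @param h an [hmatrix()].
#' @param s percept of the edge used this turn.
#' @param a action of the edge used this turn.
#' @param R reward received (the environment issues 0 or 1; any
#'   non-negative value is accepted).
#' @param gamma forgetting rate in \[0, 1\].
#' @return the updated [hmatrix()].
#' @export
update_memory <- function(h, s, a, R, gamma) {
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R < 0)
    stop("reward `R` must be a single non-negative number")
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1)
    stop("forgetting `gamma` must lie in [0, 1]")
  out <- 1 + (1 - gamma) * (unclass(h) - 1)
  i <- p_idx(s); j <- a_idx(a)
  out[i, j] <- out[i, j] + R
  hmatrix(out)
}

#' Ensemble-averaged policy
#'
#' Averages the memories of a group of agents into a single table, either
#' on the native h-value scale (entry-wise arithmetic mean of h, the
#' default) or on the probability scale (mean of the per-agent response
#' probabilities). The h-average is itself a valid h-matrix and can be fed
#' back into the kernel/mean-field machinery as a frozen policy.
#'
#' @param memories a list of [hmatrix()] objects, or a 5 x 2 x n array.
#' @param what `"h"` (default) or `"probability"`.
#' @return for `"h"`, an [hmatrix()]; for `"probability"`, a 5 x 2 matrix
#'   whose rows sum to 1.
#' @export
average_policy <- function(memories, what = c("h", "probability")) {
  what <- match.arg(what)
  if (is.array(memories) && length(dim(memories)) == 3L) {
    arr <- memories
  } else if (is.list(memories) && length(memories) > 0L) {
    arr <- array(unlist(lapply(memories, unclass)),
                 dim = c(5L, 2L, length(memories)))
  } else {
    stop("`memories` must be a non-empty list of h-matrices or a 5 x 2 x n array")
  }
  if (!identical(dim(arr)[1:2], c(5L, 2L)))
    stop("each memory must be 5 x 2")
  if (what == "h") {
    hmatrix(apply(arr, c(1, 2), mean))
  } else {
    probs <- apply(arr, 3L, function(m) m / rowSums(m), simplify = FALSE)
    out <- Reduce(`+`, probs) / length(probs)
    dimnames(out) <- list(s = as.character(PERCEPTS), a = as.character(ACTIONS))
    out
  }
}

#' Write / read an h-matrix as CSV
#'
#' Serialises the 5 x 2 table with percept row labels and action column
#' labels, for snapshotting and fixtures.
#'
#' @param h an [hmatrix()].
#' @param path file path.
#' @return `read_hmatrix` returns an [hmatrix()].
#' @export
write_hmatrix <- function(h, path) {
  df <- data.frame(s = PERCEPTS, unclass(h), check.names = FALSE)
  names(df) <- c("s", "a_turn", "a_continue")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hmatrix
#' @export
read_hmatrix <- function(path) {
  df <- read.csv(path)
  if (!identical(names(df), c("s", "a_turn", "a_continue")) ||
      nrow(df) != 5L || !identical(as.integer(df$s), PERCEPTS))
    stop("not an h-matrix CSV (expected columns s, a_turn, a_continue)")
  hmatrix(cbind(df$a_turn, df$a_continue))
}
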