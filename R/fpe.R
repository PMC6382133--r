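#' Alignment grid
#'
#' The alignment parameter of an `N`-agent swarm lives on the grid
#' `(2m - N)/N`, m = 0..N (spacing 2/N).
#'
#' @param N population size.
#' @return numeric vector of length `N + 1`.
#' @export
z_grid <- function(N) (2 * (0:N) - N) / N

#' Swarm conditioned on a given alignment
#'
#' Draws a swarm with exactly `N (1 + z) / 2` agents heading +1 (the rest
#' -1, assignment random) and i.i.d. uniform positions; every agent
#' carries the supplied fixed policy. Used to build transition kernels
#' row by row.
#'
#' @param z alignment value on the grid of [z_grid()].
#' @param cfg a [world_config()].
#' @param policy an [hmatrix()].
#' @return a [swarm_state()] with `alignment(swarm) == z`.
#' @export
sample_conditioned_swarm <- function(z, cfg, policy = make_neutral_memory()) {
  m <- (z * cfg$N + cfg$N) / 2
  if (abs(m - round(m)) > 1e-9 || m < 0 || m > cfg$N)
    stop("`z` must lie on the grid (2m - N)/N")
  m <- as.integer(round(m))
  position <- as.integer(floor(runif(cfg$N) * cfg$W))
  heading <- sample(c(rep(1L, m), rep(-1L, cfg$N - m)))
  swarm_state(position, heading, policy, cfg)
}

#' Monte-Carlo transition kernel of the alignment parameter
#'
#' For every grid value `z`, draws `n_samples` conditioned swarms
#' (uniform positions, exact heading count), applies one asynchronous
#' sweep of the fixed policy — no learning — and histograms the resulting
#' alignment `z'`. Rows of the returned matrix are normalised to
#' probabilities.
#'
#' @param cfg a [world_config()].
#' @param policy an [hmatrix()] shared by all agents.
#' @param n_samples Monte-Carlo samples per grid row.
#' @param reward_ties,move passed to the sweep (rewards do not influence
#'   fixed-mode dynamics; they are accepted for interface symmetry).
#' @param seed optional integer seed.
#' @return a `transition_kernel`: list with `grid`, row-stochastic matrix
#'   `P` (rows: initial `z`, columns: `z'`), per-row sample `counts`, and
#'   the configuration.
#' @export
estimate_transition_kernel <- function(cfg, policy, n_samples = 1000L,
                                       reward_ties = FALSE,
                                       move = c("per_sweep", "per_turn"),
                                       seed = NULL) {
  move <- match.arg(move)
  stopifnot(n_samples >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- cpp_estimate_kernel(cfg$N, cfg$W, cfg$r, as.numeric(policy),
                                as.integer(n_samples), reward_ties,
                                move == "per_turn")
  P <- counts / rowSums(counts)
  grid <- z_grid(cfg$N)
  dimnames(P) <- list(z = signif(grid, 4), zprime = signif(grid, 4))
  structure(list(grid = grid, P = P, counts = rowSums(counts),
                 cfg = cfg, policy = policy),
            class = "transition_kernel")
}

#' @export
print.transition_kernel <- function(x, ...) {
  cat(sprintf("<transition_kernel> N = %d (%d grid points), %d samples/row\n",
              x$cfg$N, length(x$grid), x$counts[1]))
  invisible(x)
}

dd_curves <- function(z, F, D, se_F = NA_real_, se_D = NA_real_, method) {
  out <- data.frame(z = z, F = F, D = D, se_F = se_F, se_D = se_D)
  attr(out, "method") <- method
  class(out) <- c("dd_curves", "data.frame")
  out
}

#' Drift and diffusion from a transition kernel
#'
#' Kramers-Moyal coefficients of the alignment parameter per time-step
#' (one sweep): drift `F(z) = E[z' - z | z]` and diffusion
#' `D(z) = (1/2) E[(z' - z - F(z))^2 | z]` (central second conditional
#' moment; the non-central variant, which differs by `F^2/2`, is available
#' via `central = FALSE`). Monte-Carlo standard errors are derived from
#' the kernel's own moments.
#'
#' @param kernel a [estimate_transition_kernel()] result.
#' @param central use the central second moment (default)?
#' @return a `dd_curves` data frame: `z`, `F`, `D`, `se_F`, `se_D`, with
#'   attribute `method = "kernel"`.
#' @export
km_from_kernel <- function(kernel, central = TRUE) {
  grid <- kernel$grid
  n <- kernel$counts
  if (any(n == 0)) stop("kernel has empty rows")
  Fz <- Dz <- seF <- seD <- numeric(length(grid))
  for (i in seq_along(grid)) {
    dz <- grid - grid[i]
    p <- kernel$P[i, ]
    Fz[i] <- sum(p * dz)
    m2c <- sum(p * (dz - Fz[i])^2)
    m4c <- sum(p * (dz - Fz[i])^4)
    Dz[i] <- if (central) m2c / 2 else sum(p * dz^2) / 2
    seF[i] <- sqrt(m2c / n[i])
    seD[i] <- 0.5 * sqrt(max(m4c - m2c^2, 0) / n[i])
  }
  dd_curves(grid, Fz, Dz, seF, seD, method = "kernel")
}

#' Mean-field drift and diffusion
#'
#' Computes the one-sweep drift and diffusion of the alignment parameter
#' analytically from the individual-level rules, under a mean-field
#' approximation that ignores within-sweep sequential feedback and
#' position-heading correlations: the focal agent sees
#' `k ~ Binomial(N - 1, 1/B)` neighbours whose headings are i.i.d. `+1`
#' with probability `(1 + z)/2`; its percept is the clipped net flow and
#' its turning probability follows from normalising the policy's
#' h-values. All sums are exact (finite binomial support).
#'
#' For a neutral policy (`d = 0`) this reduces to the closed forms
#' `F(z) = -z` and `D(z) = 1/(2N)`.
#'
#' @param N population size (integer, at least 2).
#' @param B number of non-overlapping neighbourhoods `W/(2r)`.
#' @param policy an [hmatrix()].
#' @return a `dd_curves` data frame with attribute `method = "meanfield"`.
#' @export
meanfield_drift_diffusion <- function(N, B, policy) {
  if (N != round(N) || N < 2) stop("`N` must be an integer >= 2")
  if (B <= 0) stop("`B` must be positive")
  N <- as.integer(N)
  p_in <- min(1, 1 / B)
  p_turn <- vapply(PERCEPTS, function(s) action_probabilities(policy, s)[[1L]],
                   numeric(1))  # P(a = -1 | s), s = -2..+2
  grid <- z_grid(N)
  kk <- 0:(N - 1)
  pk <- dbinom(kk, N - 1, p_in)
  q_of <- function(sigma, z) {
    pp <- (1 + z) / 2
    q <- 0
    for (k in kk) {
      if (pk[k + 1] == 0) next
      np <- 0:k
      pn <- dbinom(np, k, pp)
      s <- pmax(-2L, pmin(2L, sigma * (2L * np - k)))
      q <- q + pk[k + 1] * sum(pn * p_turn[s + 3L])
    }
    q
  }
  Fz <- Dz <- numeric(length(grid))
  for (i in seq_along(grid)) {
    z <- grid[i]
    gplus <- 1 - 2 * q_of(+1L, z)   # E[sigma' | sigma = +1] = +gplus
    gminus <- 1 - 2 * q_of(-1L, z)  # E[sigma' | sigma = -1] = -gminus
    wplus <- (1 + z) / 2
    wminus <- (1 - z) / 2
    Ez <- wplus * gplus - wminus * gminus
    Fz[i] <- Ez - z
    Dz[i] <- (1 - (wplus * gplus^2 + wminus * gminus^2)) / (2 * N)
  }
  dd_curves(grid, Fz, Dz, method = "meanfield")
}

#' Empirical drift and diffusion from a trajectory
#'
#' Bins observed one-step increments `(z_t, z_{t+1} - z_t)` of a long
#' simulated trajectory after a burn-in and estimates the Kramers-Moyal
#' coefficients per visited grid value: the conditional mean gives `F`,
#' half the conditional central variance gives `D`. Bins visited fewer
#' than `min_count` times are flagged.
#'
#' @param record a `ps_trajectory` (or any list with a `z` series).
#' @param burn_in number of initial sweeps to discard.
#' @param min_count minimum visits for a trusted bin (default 10).
#' @return a `dd_curves` data frame restricted to visited bins, with
#'   columns `n` (visits) and `trusted`, attribute `method = "empirical"`.
#' @export
empirical_km <- function(record, burn_in = 0L, min_count = 10L) {
  z <- record$z
  if (length(z) <= burn_in + 1L)
    stop("trajectory shorter than burn-in: nothing to estimate from")
  z <- z[(burn_in + 1L):length(z)]
  from <- z[-length(z)]
  dz <- diff(z)
  sp <- split(dz, from)
  zz <- as.numeric(names(sp))
  o <- order(zz)
  zz <- zz[o]; sp <- sp[o]
  n <- lengths(sp)
  Fz <- vapply(sp, mean, numeric(1))
  m2c <- mapply(function(d, f) mean((d - f)^2), sp, Fz)
  seF <- sqrt(m2c / n)
  m4c <- mapply(function(d, f) mean((d - f)^4), sp, Fz)
  seD <- 0.5 * sqrt(pmax(m4c - m2c^2, 0) / n)
  out <- dd_curves(zz, unname(Fz), unname(m2c) / 2, unname(seF),
                   unname(seD), method = "empirical")
  out$n <- as.integer(n)
  out$trusted <- n >= min_count
  out
}

#' Fixed points of the drift function
#'
#' Locates zeros of `F(z)` by linear interpolation between adjacent grid
#' points where the sign changes (grid points where `F` is exactly zero
#' count as roots directly). The slope `dF/dz` at each root is taken from
#' centred finite differences, interpolated to the root; a root is stable
#' iff the slope is negative. For Monte-Carlo curves carrying standard
#' errors, a root in whose neighbourhood `|F|` never exceeds twice its
#' standard error is flagged low-confidence.
#'
#' @param curves a `dd_curves` data frame.
#' @return a `fixed_points` data frame: `z0`, `slope`, `stability`,
#'   `low_confidence`. If `F` is identically zero the result is empty
#'   with attribute `degenerate = TRUE` (the whole line is fixed).
#' @export
find_fixed_points <- function(curves) {
  z <- curves$z; F <- curves$F
  n <- length(z)
  if (n < 2L) stop("need at least two grid points")
  empty <- data.frame(z0 = numeric(0), slope = numeric(0),
                      stability = character(0), low_confidence = logical(0))
  if (all(F == 0)) {
    attr(empty, "degenerate") <- TRUE
    class(empty) <- c("fixed_points", "data.frame")
    return(empty)
  }
  # centred-difference slope on the grid (one-sided at the ends)
  slope_grid <- c((F[2] - F[1]) / (z[2] - z[1]),
                  (F[3:n] - F[1:(n - 2)]) / (z[3:n] - z[1:(n - 2)]),
                  (F[n] - F[n - 1]) / (z[n] - z[n - 1]))
  interp <- function(x, x0, x1, y0, y1) y0 + (y1 - y0) * (x - x0) / (x1 - x0)
  roots <- numeric(0)
  for (i in seq_len(n)) {
    if (F[i] == 0) roots <- c(roots, z[i])
    else if (i < n && F[i] * F[i + 1] < 0)
      roots <- c(roots, z[i] - F[i] * (z[i + 1] - z[i]) / (F[i + 1] - F[i]))
  }
  roots <- sort(unique(roots))
  slope <- vapply(roots, function(r) {
    j <- findInterval(r, z, all.inside = TRUE)
    interp(r, z[j], z[j + 1], slope_grid[j], slope_grid[j + 1])
  }, numeric(1))
  lowconf <- vapply(roots, function(r) {
    if (is.null(curves$se_F) || all(is.na(curves$se_F))) return(FALSE)
    j <- findInterval(r, z, all.inside = TRUE)
    win <- max(1, j - 2):min(n, j + 3)
    all(abs(F[win]) <= 2 * curves$se_F[win])
  }, logical(1))
  out <- data.frame(z0 = roots, slope = slope,
                    stability = ifelse(slope < 0, "stable", "unstable"),
                    low_confidence = lowconf)
  attr(out, "degenerate") <- FALSE
  class(out) <- c("fixed_points", "data.frame")
  out
}

#' Write drift/diffusion curves or kernels as CSV
#'
#' `write_dd_curves` emits `z,F,D,se_F,se_D,method`; `write_kernel` emits
#' the long format `z,zprime,p`; `write_fixed_points` emits
#' `z0,slope,stability`.
#'
#' @param curves,kernel,fp the respective objects.
#' @param path output path.
#' @export
write_dd_curves <- function(curves, path) {
  df <- as.data.frame(curves)[, c("z", "F", "D", "se_F", "se_D")]
  df$method <- attr(curves, "method")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dd_curves
#' @export
write_kernel <- function(kernel, path) {
  g <- kernel$grid
  df <- data.frame(z = rep(g, each = length(g)),
                   zprime = rep(g, times = length(g)),
                   p = as.vector(t(kernel$P)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dd_curves
#' @export
write_fixed_points <- function(fp, path) {
  write.csv(as.data.frame(fp)[, c("z0", "slope", "stability")], path,
            row.names = FALSE)
  invisible(path)
}
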