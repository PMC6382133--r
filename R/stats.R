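#' Learning curves from memory snapshots
#'
#' Tracks how the ensemble's response probabilities develop during
#' training. For each snapshot time, the response probability of every
#' agent is computed from its h-matrix and averaged across the ensemble;
#' the default tracked responses are maintaining direction under an
#' aligned net flow (`s = +2, a = +1`), turning around when facing an
#' opposing net flow (`s = -2, a = -1`), and turning on zero net flow
#' (`s = 0, a = -1`) — the latter is expected to stay near one half.
#'
#' @param record a `ps_trajectory` produced with `record = "memory"`, or a
#'   list of 5 x 2 x N snapshot arrays plus `times`.
#' @param pairs data frame with columns `s`, `a` selecting tracked
#'   percept-action pairs.
#' @param times snapshot times (taken from the record when omitted).
#' @return a `learning_curve` data frame: `t`, `s`, `a`, `p_mean`, `p_sd`.
#' @export
learning_curves <- function(record,
                            pairs = data.frame(s = c(2L, -2L, 0L),
                                               a = c(1L, -1L, -1L)),
                            times = NULL) {
  if (inherits(record, "ps_trajectory")) {
    snaps <- record$snapshots
    times <- record$snapshot_t
  } else {
    snaps <- record
  }
  if (is.null(snaps) || length(snaps) < 2L)
    stop("need memory snapshots at two or more times (record = \"memory\")")
  if (is.null(times)) times <- seq_along(snaps) - 1L
  res <- lapply(seq_along(snaps), function(k) {
    arr <- snaps[[k]]
    per_pair <- lapply(seq_len(nrow(pairs)), function(j) {
      i <- p_idx(pairs$s[j]); a <- a_idx(pairs$a[j])
      p <- arr[i, a, ] / (arr[i, 1, ] + arr[i, 2, ])
      data.frame(t = times[k], s = pairs$s[j], a = pairs$a[j],
                 p_mean = mean(p), p_sd = sd(p))
    })
    do.call(rbind, per_pair)
  })
  out <- do.call(rbind, res)
  class(out) <- c("learning_curve", "data.frame")
  out
}

#' Directional switching statistics
#'
#' Counts reversals of the group's marching direction with a two-threshold
#' hysteresis rule: a switch is registered whenever the alignment series
#' crosses from at or below `-theta` to at or above `+theta` or vice
#' versa, so small fluctuations around zero are not counted. Dwell times
#' are the gaps between consecutive switches.
#'
#' @param z alignment series (or a `ps_trajectory`).
#' @param theta hysteresis threshold in (0, 1), default 0.3.
#' @param window indices of `z` to analyse (default: all).
#' @return a `regime_summary`: list with `mean_abs_z`, `switches`,
#'   `switch_rate` (per sweep), `dwell_times`, `mean_dwell`, `n_steps`,
#'   and a regime `label` from [regime_classify()].
#' @export
switching_statistics <- function(z, theta = 0.3, window = NULL) {
  if (inherits(z, "ps_trajectory")) z <- z$z
  if (length(z) == 0L) stop("empty alignment series")
  if (theta <= 0 || theta >= 1) stop("`theta` must lie in (0, 1)")
  if (!is.null(window)) z <- z[window]
  side <- 0L  # last armed side: -1, +1, or 0 before first excursion
  switch_at <- integer(0)
  for (i in seq_along(z)) {
    s <- if (z[i] >= theta) 1L else if (z[i] <= -theta) -1L else 0L
    if (s != 0L) {
      if (side != 0L && s != side) switch_at <- c(switch_at, i)
      side <- s
    }
  }
  dwell <- diff(switch_at)
  out <- list(mean_abs_z = mean(abs(z)),
              switches = length(switch_at),
              switch_rate = length(switch_at) / length(z),
              dwell_times = dwell,
              mean_dwell = if (length(dwell)) mean(dwell) else NA_real_,
              n_steps = length(z),
              theta = theta)
  out$label <- regime_classify(out)
  class(out) <- "regime_summary"
  out
}

#' @export
print.regime_summary <- function(x, ...) {
  cat(sprintf("<regime_summary> mean |z| = %.3f, %d switches in %d steps (%s)\n",
              x$mean_abs_z, x$switches, x$n_steps, x$label))
  invisible(x)
}

#' Classify the collective-motion regime
#'
#' Operational definition of the three regimes seen across densities:
#' `disordered` when the time-averaged |z| is below `disorder_max`;
#' `ordered` when it is at least `order_min` and direction switches are
#' rarer than `max_order_switch_rate`; `intermediate` otherwise (global
#' alignment with stochastic direction changes).
#'
#' @param summary a `regime_summary` from [switching_statistics()] (or a
#'   list with `mean_abs_z` and `switch_rate`).
#' @param disorder_max upper mean-|z| bound for disorder (default 0.3).
#' @param order_min lower mean-|z| bound for order (default 0.6).
#' @param max_order_switch_rate maximal switch rate still called ordered,
#'   per sweep (default 1/1000).
#' @return `"disordered"`, `"intermediate"` or `"ordered"`.
#' @export
regime_classify <- function(summary, disorder_max = 0.3, order_min = 0.6,
                            max_order_switch_rate = 1e-3) {
  if (summary$mean_abs_z < disorder_max) "disordered"
  else if (summary$mean_abs_z >= order_min &&
           summary$switch_rate < max_order_switch_rate) "ordered"
  else "intermediate"
}

#' Write learning curves / regime summaries as CSV
#'
#' @param curves a `learning_curve` data frame.
#' @param summaries a list of `regime_summary` objects (names become
#'   `run_id`s).
#' @param path output path.
#' @export
write_learning_curves <- function(curves, path) {
  write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_learning_curves
#' @export
write_regimes <- function(summaries, path) {
  if (inherits(summaries, "regime_summary")) summaries <- list(summaries)
  ids <- names(summaries)
  if (is.null(ids)) ids <- as.character(seq_along(summaries))
  df <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    data.frame(run_id = ids[i], mean_abs_z = s$mean_abs_z,
               switches = s$switches, label = s$label)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
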