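#' Stochastic single-channel simulation
#'
#' Samples an exact trajectory of the gating chain (exponential sojourns,
#' embedded-chain jumps) with R's seeded RNG. The initial state is drawn from
#' the equilibrium distribution unless `start` is given.
#'
#' @param mech a [mechanism()] or `q_matrix`.
#' @param concentrations ligand concentrations for Q assembly.
#' @param n_transitions number of state transitions to simulate (the
#'   trajectory visits `n_transitions + 1` states), or `NULL` to simulate by
#'   duration.
#' @param duration total simulated time in seconds (used when
#'   `n_transitions` is `NULL`).
#' @param seed integer seed recorded in the output; when `NULL` the current
#'   RNG stream is used (and no seed is recorded).
#' @param start optional initial state id.
#' @return Object of class `trajectory`: list with `states` (ids visited),
#'   `durations` (sojourns, s), `classes`, `seed`.
#' @export
simulate_trajectory <- function(mech, concentrations = numeric(0),
                                n_transitions = NULL, duration = NULL,
                                seed = NULL, start = NULL) {
  q <- as_q(mech, concentrations)
  if (is.null(n_transitions) && is.null(duration))
    stop("give n_transitions or duration")
  if (!is.null(seed)) set.seed(seed)
  p <- equilibrium_dist(q)
  s0 <- if (is.null(start)) sample(length(p), 1L, prob = p)
        else match(start, q$states)
  if (is.na(s0)) stop("unknown start state")
  sim <- sim_ctmc(q$Q, s0, if (is.null(n_transitions)) -1L
                  else as.integer(n_transitions),
                  if (is.null(duration)) 0 else duration)
  structure(list(states = q$states[sim$states],
                 durations = sim$durations,
                 classes = q$class[sim$states],
                 seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$states), " sojourns, ",
      signif(sum(x$durations), 4), " s total",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), "\n", sep = "")
  invisible(x)
}

#' Collapse a trajectory to alternating open/shut dwells
#'
#' Merges consecutive sojourns in the same conductance class and trims the
#' record to begin with an opening and end with a closing. Total merged time
#' is conserved; the result is an unresolved [dwell_sequence()] (apply
#' [impose_resolution()] before likelihood work).
#'
#' @param traj a [simulate_trajectory()] result.
#' @return A [dwell_sequence()] with a single segment.
#' @export
to_dwells <- function(traj) {
  r <- rle(traj$classes)
  if (!any(r$values == "open")) stop("trajectory never opens")
  dur <- as.numeric(rowsum(traj$durations,
                           rep(seq_along(r$lengths), r$lengths)))
  cl <- r$values
  i1 <- match("open", cl)
  i2 <- max(which(cl == "shut"))
  if (i2 < i1) stop("trajectory has no closing after its first opening")
  dwell_sequence(dur[i1:i2], cl[i1:i2])
}

#' Simulate a multi-patch synthetic data set
#'
#' Convenience wrapper producing several independent records from one
#' mechanism under a single seeded RNG stream, mirroring a data set of
#' several one-channel patches. Defaults give four records of about 27,000
#' transitions each.
#'
#' @inheritParams simulate_trajectory
#' @param n_patches number of records.
#' @param transitions_per_patch open-closed transitions per record: the
#'   number of dwells after class merging (and after resolution imposition
#'   when `dt` is given). The underlying trajectory is grown until the record
#'   holds this many resolved dwells.
#' @param dt optional [dead_times()]; when given, resolution is imposed on
#'   the merged dwells.
#' @return A [dwell_sequence()] with one segment per patch.
#' @export
simulate_patches <- function(mech, concentrations = numeric(0),
                             n_patches = 4, transitions_per_patch = 27000,
                             seed = 1, dt = NULL) {
  set.seed(seed)
  q <- as_q(mech, concentrations)
  one_patch <- function() {
    n_raw <- transitions_per_patch * 4
    repeat {
      d <- to_dwells(simulate_trajectory(q, n_transitions = n_raw))
      if (!is.null(dt)) d <- impose_resolution(d, dt)
      if (nrow(d) >= transitions_per_patch) {
        d <- as.data.frame(d)[seq_len(transitions_per_patch), , drop = FALSE]
        while (d$class[nrow(d)] != "shut") d <- d[-nrow(d), , drop = FALSE]
        return(dwell_sequence(d$duration, d$class, resolution = dt))
      }
      n_raw <- ceiling(n_raw * max(1.5, 1.25 * transitions_per_patch /
                                     max(nrow(d), 1)))
    }
  }
  segs <- lapply(seq_len(n_patches), function(i) one_patch())
  out <- do.call(rbind, lapply(seq_along(segs), function(i) {
    df <- as.data.frame(segs[[i]])
    df$segment <- i
    df
  }))
  dwell_sequence(out$duration, out$class, segment = out$segment,
                 resolution = if (!is.null(dt)) dt)
}
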