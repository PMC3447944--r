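# Stochastic reference simulators. Both are deliberately independent of
# the analytic machinery they are used to validate: the walker simulator
# never touches the transition-matrix code, and the Brownian simulator
# never evaluates the inverse-Gaussian formulas.

#' Simulate first-passage times of random walkers
#'
#' Direct agent simulation of the node walk: each walker starts at vertex 1
#' (reflecting) and the passage time is the step at which it first reaches
#' vertex n. Used as a Monte-Carlo reference for the matrix first-passage
#' computation.
#'
#' @param params An [mc_params()].
#' @param n_walkers Number of walkers.
#' @param k_max Step cap; walkers still in transit are reported in
#'   `n_censored`.
#' @param seed Integer seed.
#' @return List: `steps` (integer passage steps of arrived walkers),
#'   `n_censored`.
#' @export
simulate_walkers <- function(params, n_walkers = 1e5, k_max = 5000, seed = 1) {
  stopifnot(inherits(params, "mc_params"))
  set.seed(seed)
  nv <- params$n_vertices
  pos <- rep(1L, n_walkers)
  arrived_at <- integer(0)
  active <- seq_len(n_walkers)
  for (k in seq_len(k_max)) {
    u <- runif(length(active))
    step <- ifelse(u < params$q_fwd, 1L,
                   ifelse(u < params$q_fwd + params$q_bwd, -1L, 0L))
    pos[active] <- pmax(pos[active] + step, 1L)
    done <- pos[active] >= nv
    if (any(done)) {
      arrived_at <- c(arrived_at, rep.int(k, sum(done)))
      active <- active[!done]
    }
    if (!length(active)) break
  }
  list(steps = arrived_at, n_censored = length(active))
}

#' Simulate Brownian first-passage times
#'
#' Euler-Maruyama simulation of one-dimensional Brownian motion with drift
#' `v` and unit diffusion, started at 0, absorbed at barrier `d`, with a
#' Brownian-bridge crossing check inside every step (the probability that
#' the bridge between two sub-barrier endpoints crossed the barrier is
#' exp(-2 (d - x0)(d - x1) / dt)), which removes the O(sqrt(dt)) boundary
#' bias of the naive scheme.
#'
#' @param d Barrier distance (> 0).
#' @param v Drift per hour (> 0 for finite passage).
#' @param n_paths Number of paths.
#' @param dt Time step in hours (default 0.01).
#' @param t_max Censoring horizon in hours.
#' @param seed Integer seed.
#' @return List: `times` (passage times in hours of absorbed paths),
#'   `n_censored`.
#' @export
brownian_first_passage <- function(d, v, n_paths = 1e5, dt = 0.01,
                                   t_max = 200, seed = 1) {
  stopifnot(d > 0)
  set.seed(seed)
  x <- numeric(n_paths)
  active <- seq_len(n_paths)
  times <- numeric(0)
  n_steps <- ceiling(t_max / dt)
  sq <- sqrt(dt)
  for (k in seq_len(n_steps)) {
    m <- length(active)
    x_new <- x[active] + v * dt + sq * rnorm(m)
    crossed <- x_new >= d
    # bridge correction for paths ending below the barrier
    below <- !crossed
    if (any(below)) {
      p_bridge <- exp(-2 * (d - x[active][below]) *
                        (d - x_new[below]) / dt)
      crossed[below] <- runif(sum(below)) < p_bridge
    }
    if (any(crossed)) {
      times <- c(times, rep.int(k * dt, sum(crossed)))
      keep <- !crossed
      x[active[keep]] <- x_new[keep]
      active <- active[keep]
    } else {
      x[active] <- x_new
    }
    if (!length(active)) break
  }
  list(times = times, n_censored = length(active))
}
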