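# Discrete one-dimensional Markov-chain random walk through the node:
# vertex 1 models the high endothelial venules (entry), vertex n the exit
# into the efferent lymphatic. Per step a cell moves forward (q_fwd),
# backward (q_bwd) or stays (q_stay); each step lasts dt_min minutes.

#' Random-walk parameters
#'
#' @param q_fwd,q_bwd,q_stay Per-step probabilities of moving to the next
#'   vertex, the previous vertex, or staying. Must be nonnegative and sum
#'   to 1; `q_stay` defaults to the complement. `q_fwd` must be positive.
#' @param n_vertices Number of vertices (>= 2).
#' @param dt_min Step duration in minutes.
#' @return A list of class `mc_params`.
#' @export
mc_params <- function(q_fwd, q_bwd, q_stay = 1 - q_fwd - q_bwd,
                      n_vertices, dt_min) {
  if (q_fwd <= 0) stop("q_fwd must be positive")
  if (min(q_fwd, q_bwd, q_stay) < -1e-12) stop("probabilities must be >= 0")
  if (abs(q_fwd + q_bwd + q_stay - 1) > 1e-12)
    stop("probabilities must sum to 1")
  if (n_vertices < 2) stop("need at least 2 vertices")
  if (dt_min <= 0) stop("dt_min must be positive")
  structure(list(q_fwd = q_fwd, q_bwd = q_bwd, q_stay = max(q_stay, 0),
                 n_vertices = as.integer(n_vertices), dt_min = dt_min),
            class = "mc_params")
}

#' @export
print.mc_params <- function(x, ...) {
  cat(sprintf("<mc_params> q_fwd %.3g, q_bwd %.3g, q_stay %.3g; %d vertices, dt %g min\n",
              x$q_fwd, x$q_bwd, x$q_stay, x$n_vertices, x$dt_min))
  invisible(x)
}

#' Transition matrix of the walk
#'
#' Interior vertices move forward/backward/stay with the three
#' probabilities; vertex 1 is reflecting (backward folds into staying) and
#' vertex n is absorbing, so that the (1, n) entry of the k-step matrix
#' gives the cumulative first-passage probability.
#'
#' @param params An [mc_params()].
#' @return An n x n row-stochastic matrix.
#' @export
build_transition_matrix <- function(params) {
  stopifnot(inherits(params, "mc_params"))
  n <- params$n_vertices
  P <- matrix(0, n, n)
  P[1, 1] <- params$q_stay + params$q_bwd
  P[1, min(2, n)] <- P[1, min(2, n)] + params$q_fwd
  if (n > 2) {
    for (i in 2:(n - 1)) {
      P[i, i - 1] <- params$q_bwd
      P[i, i] <- params$q_stay
      P[i, i + 1] <- params$q_fwd
    }
  }
  P[n, ] <- 0
  P[n, n] <- 1
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("rows of the transition matrix must sum to 1")
  P
}

#' First-passage-time law of the walk
#'
#' With the terminal vertex absorbing, the (1, n) entry of the k-step matrix is the probability of
#' having arrived by step k; the law f_k is its increment. Computed by
#' iterated vector-matrix products (never dense matrix powers).
#'
#' @param P Transition matrix from [build_transition_matrix()].
#' @param k_max Number of steps to evaluate (>= 1).
#' @param dt_min Step duration in minutes carried along for binning.
#' @return A list of class `first_passage_law`: `f` (length `k_max`),
#'   `dt_min`, `tail_mass` (probability of non-arrival by `k_max`).
#' @export
first_passage_distribution <- function(P, k_max, dt_min = NA_real_) {
  if (k_max < 1) stop("k_max must be >= 1")
  n <- nrow(P)
  if (abs(P[n, n] - 1) > 1e-12) stop("terminal vertex must be absorbing")
  res <- fp_law_dense(P, as.integer(k_max))
  structure(list(f = res$f, dt_min = dt_min, tail_mass = res$tail_mass),
            class = "first_passage_law")
}

# Fast path used in grid searches: same law from raw parameters.
fp_law_params <- function(params, k_max) {
  res <- fp_law_tridiag(params$q_fwd, params$q_bwd, params$q_stay,
                        params$n_vertices, as.integer(k_max))
  structure(list(f = res$f, dt_min = params$dt_min,
                 tail_mass = res$tail_mass),
            class = "first_passage_law")
}

#' Bin a first-passage law onto the 2-hour grid
#'
#' The probability of the bin (t-2, t] hours is the sum of f_k over steps k
#' with k dt_min in ((t-2) 60, t 60] minutes. Mass beyond 100 h (including
#' the law's own non-arrival tail) is reported as `tail_mass` and excluded
#' from p without renormalisation.
#'
#' @param law A `first_passage_law` with `dt_min` set.
#' @return A [transit_distribution()] with origin `"mc"`.
#' @export
bin_to_hours <- function(law) {
  stopifnot(inherits(law, "first_passage_law"))
  if (is.na(law$dt_min)) stop("law must carry dt_min for binning")
  k <- seq_along(law$f)
  t_min <- k * law$dt_min
  # bin index 1..50 for (0,120], ..., i.e. ceiling of t_h / 2
  bin <- ceiling(t_min / (BIN_W * 60) - 1e-12)
  inside <- bin >= 1 & bin <= N_BINS
  p <- numeric(N_BINS)
  if (any(inside)) {
    agg <- tapply(law$f[inside], bin[inside], sum)
    p[as.integer(names(agg))] <- agg
  }
  beyond <- sum(law$f[!inside]) + law$tail_mass
  stopifnot(abs(sum(p) + beyond - 1) < 1e-9)
  transit_distribution(p, origin = "mc", tail_mass = beyond)
}

#' Mean transit time implied by a first-passage law
#'
#' Sum of k f_k dt, in hours. Only meaningful when the non-arrival tail is
#' negligible.
#'
#' @param law A `first_passage_law` with `dt_min`.
#' @return Mean first-passage time in hours.
#' @export
mean_first_passage_h <- function(law) {
  stopifnot(inherits(law, "first_passage_law"))
  sum(seq_along(law$f) * law$f) * law$dt_min / 60
}

# Mean time in the node for the reinjection reading of the chain, where a
# cell occupies vertex n and leaves with probability q_fwd per step
# (the absorb-on-arrival law above ends one holding time earlier).
mc_mean_exit_h <- function(params) {
  n <- params$n_vertices
  qf <- params$q_fwd; qb <- params$q_bwd; qs <- params$q_stay
  # m_i = expected remaining steps from vertex i until exit from vertex n
  A <- matrix(0, n, n); b <- rep(1, n)
  A[1, 1] <- 1 - (qs + qb); if (n >= 2) A[1, 2] <- -qf
  if (n > 2) for (i in 2:(n - 1)) {
    A[i, i - 1] <- -qb; A[i, i] <- 1 - qs; A[i, i + 1] <- -qf
  }
  A[n, n - 1] <- -qb; A[n, n] <- 1 - qs
  m <- solve(A, b)
  m[1] * params$dt_min / 60
}

#' Grid-search fit of the random walk to efflux data
#'
#' Two-stage exhaustive search. Stage 1 scans `q_stay`, the drift ratio
#' `q_fwd/q_bwd`, the vertex count and the step duration; the objective is
#' the total SSE of predicted efflux c B p(params) against L over the
#' training systems. Stage 2 fixes `q_stay`, n and dt at their stage-1
#' optima and refines (`q_fwd`, `q_bwd`) on a 0.01 grid. Also returns the
#' SSE surface on the (q_stay, ratio) plane at the optimal n and dt, for
#' the drift heat map.
#'
#' @param systems Training list of `convolution_system`s with `c` estimated.
#' @param q_stay_grid,ratio_grid,n_grid,dt_grid Stage-1 grids. Defaults:
#'   q_stay 0 to 0.9 by 0.1; ratio {1/4, 1/2, 2/3, 1, 3/2, 2, 4};
#'   n {5, 10, ..., 50}; dt {1, 2, 5, 10} minutes.
#' @param refine_step Stage-2 step on q_fwd (default 0.01).
#' @return A list: `params` (best [mc_params()]), `dist` (best binned
#'   [transit_distribution()]), `sse` (training SSE), `surface` (data frame
#'   q_stay, ratio, sse at optimal n, dt), `stage1`, `stage2` tables.
#' @export
fit_mc <- function(systems,
                   q_stay_grid = seq(0, 0.9, by = 0.1),
                   ratio_grid = c(1/4, 1/2, 2/3, 1, 3/2, 2, 4),
                   n_grid = seq(5, 50, by = 5),
                   dt_grid = c(1, 2, 5, 10),
                   refine_step = 0.01) {
  if (length(systems) < 1) stop("need at least one training system")
  if (!length(q_stay_grid) || !length(ratio_grid) || !length(n_grid) ||
      !length(dt_grid)) stop("empty grid")
  if (any(vapply(systems, function(s) is.na(s$c), logical(1))))
    stop("all systems must have c estimated")

  train_sse <- function(params) {
    law <- fp_law_params(params, k_max = ceiling(100 * 60 / params$dt_min))
    d <- bin_to_hours(law)
    list(sse = sum(vapply(systems, function(s)
           sse(predict_efflux(s, d), s$L), numeric(1))),
         dist = d)
  }
  par_from <- function(q_stay, ratio, n, dt) {
    move <- 1 - q_stay
    mc_params(q_fwd = move * ratio / (1 + ratio),
              q_bwd = move / (1 + ratio),
              n_vertices = n, dt_min = dt)
  }

  stage1 <- expand.grid(q_stay = q_stay_grid, ratio = ratio_grid,
                        n = n_grid, dt = dt_grid)
  stage1$sse <- NA_real_
  for (i in seq_len(nrow(stage1))) {
    pr <- par_from(stage1$q_stay[i], stage1$ratio[i], stage1$n[i],
                   stage1$dt[i])
    stage1$sse[i] <- train_sse(pr)$sse
  }
  b1 <- stage1[which.min(stage1$sse), ]
  surface <- stage1[stage1$n == b1$n & stage1$dt == b1$dt,
                    c("q_stay", "ratio", "sse")]
  rownames(surface) <- NULL

  # stage 2: q_stay, n, dt fixed; scan q_fwd on a fine grid
  move <- 1 - b1$q_stay
  qf_grid <- seq(refine_step, move - refine_step, by = refine_step)
  if (!length(qf_grid)) qf_grid <- move / 2
  stage2 <- data.frame(q_fwd = qf_grid, q_bwd = move - qf_grid,
                       sse = NA_real_)
  best <- list(sse = Inf)
  for (i in seq_len(nrow(stage2))) {
    pr <- mc_params(stage2$q_fwd[i], stage2$q_bwd[i],
                    n_vertices = b1$n, dt_min = b1$dt)
    r <- train_sse(pr)
    stage2$sse[i] <- r$sse
    if (r$sse < best$sse) best <- list(sse = r$sse, params = pr, dist = r$dist)
  }
  list(params = best$params, dist = best$dist, sse = best$sse,
       surface = surface, stage1 = stage1, stage2 = stage2)
}

#' Steady-state occupancy under reinjection
#'
#' During periods without antigenic challenge the number of cells leaving
#' the node equals the number entering, so the walk is closed into a loop:
#' the terminal vertex behaves as interior but its forward (exit) flux is
#' reinjected at vertex 1. Returns the stationary distribution pi of the
#' modified chain, solved from the linear system pi P' = pi, sum(pi) = 1.
#'
#' @param params An [mc_params()] (requires `q_fwd > 0` for irreducibility).
#' @return Numeric occupancy vector over vertices (sums to 1), with the
#'   modified matrix as attribute `"P"`.
#' @export
steady_state_occupancy <- function(params) {
  stopifnot(inherits(params, "mc_params"))
  if (params$q_fwd <= 0) stop("chain is not irreducible without forward moves")
  n <- params$n_vertices
  P <- build_transition_matrix(params)
  # terminal vertex: interior behaviour with forward flux recycled to 1
  P[n, ] <- 0
  P[n, n - 1] <- P[n, n - 1] + params$q_bwd
  P[n, n] <- params$q_stay
  P[n, 1] <- P[n, 1] + params$q_fwd
  stopifnot(all(abs(rowSums(P) - 1) < 1e-12))
  # pi (P' - I) = 0 with sum constraint: replace last column by ones
  M <- t(P) - diag(n)
  M[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  pi <- solve(M, b)
  if (any(pi < -1e-10)) stop("stationary solve returned negative occupancy")
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  attr(pi, "P") <- P
  pi
}
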