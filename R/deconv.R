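# Simplex-constrained (S-)LASSO deconvolution of the transit distribution.
#
# The observation model is L = c B p + noise, with B the lower-triangular
# lagged-input matrix, p on the probability simplex and c > 0 the
# input/output proportionality constant. With the nonnegativity constraint
# in place, the L1 bound ||p||_1 <= 1 of the LASSO is the simplex
# constraint sum(p) = 1, so every solve is a convex quadratic program.

# Second-difference operator (48 x 50): rows are (1, -2, 1) stencils.
# Penalising ||D p||^2 penalises curvature of the solution.
second_difference_operator <- function(n = N_BINS) {
  D <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  D
}

first_difference_operator <- function(n = N_BINS) {
  D <- matrix(0, n - 1, n)
  for (i in seq_len(n - 1)) D[i, i:(i + 1)] <- c(1, -1)
  D
}

# Core QP: minimise ||y - A p||^2 + lambda ||D p||^2 over the simplex,
# optionally with some coordinates pinned to zero (pinned variables are
# eliminated before the solve). Solved exactly by the Goldfarb-Idnani dual
# active-set method (quadprog); a relative ridge of 1e-10 keeps the Hessian
# numerically positive definite when A is ill-conditioned.
simplex_qp <- function(A, y, lambda = 0, D = NULL, zero_idx = integer(0)) {
  n <- ncol(A)
  free <- setdiff(seq_len(n), zero_idx)
  if (length(free) == 0) stop("all coordinates pinned to zero")
  if (lambda > 0 && is.null(D)) D <- second_difference_operator(n)
  Af <- A[, free, drop = FALSE]
  G <- crossprod(Af)
  if (lambda > 0) {
    Df <- D[, free, drop = FALSE]
    G <- G + lambda * crossprod(Df)
  }
  m <- length(free)
  G <- G + diag(1e-10 * max(sum(diag(G)) / m, 1), m)
  a <- crossprod(Af, y)
  Amat <- cbind(rep(1, m), diag(m))   # sum(p) = 1 (equality), then p >= 0
  bvec <- c(1, rep(0, m))
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = G, dvec = a, Amat = Amat, bvec = bvec, meq = 1L),
    error = function(e) stop("quadratic program failed: ", conditionMessage(e)))
  pf <- sol$solution
  if (any(pf < -1e-6)) stop("QP solution violates nonnegativity: min p = ",
                            min(pf))
  p <- numeric(n)
  p[free] <- pmax(pf, 0)
  p / sum(p)
}

#' Estimate the input/output proportionality constant c
#'
#' Solves the unconstrained-sum nonnegative least-squares problem
#' min ||L - B q||^2 with q >= 0 and takes c as the L1 norm of the solution
#' vector. This is the scale by which the input matrix must be multiplied so
#' that a unit-sum probability vector can explain the efflux.
#'
#' @param sys A `convolution_system` from [build_convolution_system()].
#' @return The system with `c` set (invisibly the same list; returned value
#'   is the updated system). Access the constant as `sys$c`.
#' @export
estimate_c <- function(sys) {
  stopifnot(inherits(sys, "convolution_system"))
  if (all(sys$L == 0)) stop("no signal: efflux is identically zero")
  q <- pracma::lsqnonneg(sys$B, sys$L)$x
  cc <- sum(q)
  if (cc <= 0) stop("estimated c is not positive")
  sys$c <- cc
  sys
}

#' Deconvolve the transit distribution by simplex-constrained LASSO
#'
#' Minimises ||L - c B p||^2 subject to sum(p) = 1, p >= 0. With the
#' nonnegativity constraint, the LASSO's L1 bound equals the simplex
#' constraint, so the fit is an exact convex QP: deterministic given its
#' inputs.
#'
#' @param sys A `convolution_system` with `c` estimated ([estimate_c()]).
#' @return A [transit_distribution()] with origin `"lasso"`.
#' @export
solve_lasso <- function(sys) {
  solve_slasso(sys, lambda = 0)
}

#' Smoothed simplex-constrained LASSO (S-LASSO)
#'
#' Adds a curvature penalty to [solve_lasso()]: minimises
#' ||L - c B p||^2 + lambda ||D p||^2 over the simplex, with D the
#' second-difference operator (48 x 50) by default. `lambda = 0` reduces
#' exactly to the plain LASSO solution.
#'
#' @param sys A `convolution_system` with `c` estimated.
#' @param lambda Nonnegative smoothing weight.
#' @param penalty `"second_diff"` (default) or `"first_diff"`.
#' @return A [transit_distribution()] with origin `"slasso"` (`"lasso"`
#'   when `lambda = 0`).
#' @export
solve_slasso <- function(sys, lambda, penalty = c("second_diff", "first_diff")) {
  stopifnot(inherits(sys, "convolution_system"))
  penalty <- match.arg(penalty)
  if (is.na(sys$c)) stop("estimate c first (see estimate_c)")
  if (lambda < 0) stop("lambda must be nonnegative")
  D <- if (penalty == "second_diff") second_difference_operator()
       else first_difference_operator()
  p <- simplex_qp(sys$c * sys$B, sys$L, lambda = lambda, D = D)
  transit_distribution(p, origin = if (lambda == 0) "lasso" else "slasso")
}

#' Predicted efflux from a transit distribution
#'
#' @param sys A `convolution_system` with `c` estimated.
#' @param dist A [transit_distribution()].
#' @return Length-50 vector of predicted lymph percentages c B p.
#' @export
predict_efflux <- function(sys, dist) {
  stopifnot(inherits(sys, "convolution_system"),
            inherits(dist, "transit_distribution"))
  if (is.na(sys$c)) stop("estimate c first (see estimate_c)")
  as.numeric(sys$c * (sys$B %*% dist$p))
}

# Stack systems (scaled each by its own c) into one regression.
stack_systems <- function(systems) {
  A <- do.call(rbind, lapply(systems, function(s) s$c * s$B))
  y <- unlist(lapply(systems, function(s) s$L), use.names = FALSE)
  list(A = A, y = y)
}

#' S-LASSO smoothing configuration
#'
#' @param lambda_grid Nonnegative smoothing values (sorted internally).
#'   The default is log-spaced around the smoothing levels at which held-out
#'   error typically bottoms out for three-animal training sets.
#' @param n_train Training-set size drawn per repetition (3 or 9 in the
#'   original analysis; any positive integer accepted).
#' @param n_rep Number of resampling repetitions (default 50).
#' @param seed Integer seed for the resampling.
#' @return A list of class `slasso_config`.
#' @export
slasso_config <- function(lambda_grid = c(0, 1, 2, 5, 10, 20, 50, 100, 200),
                          n_train = 3, n_rep = 50, seed = 1) {
  if (length(lambda_grid) == 0) stop("lambda_grid must be nonempty")
  if (any(lambda_grid < 0)) stop("lambda_grid must be nonnegative")
  if (n_rep < 1) stop("n_rep must be >= 1")
  structure(list(lambda_grid = sort(lambda_grid), n_train = as.integer(n_train),
                 n_rep = as.integer(n_rep), seed = as.integer(seed)),
            class = "slasso_config")
}

#' Concatenate resampled training sets and tune the smoothing weight
#'
#' Repeats `n_rep` times: draw `n_train` systems with replacement (duplicates
#' are stacked twice), stack their scaled input matrices and efflux vectors
#' into one regression, solve the S-LASSO for every lambda on the grid, and
#' score each solution by the average per-system SSE of predicted efflux on
#' the systems never drawn in that repetition (each held-out system keeps
#' its own c). Returns the overall best (repetition, lambda) distribution and
#' the per-repetition table of optima.
#'
#' @param systems List of `convolution_system`s with `c` estimated; at least
#'   `n_train + 1` of them.
#' @param cfg An [slasso_config()].
#' @return A list with `best_lambda`, `best_dist`, `best_test_sse` and
#'   `reps` (data frame: rep, lambda_opt, test_sse).
#' @export
concat_and_tune <- function(systems, cfg = slasso_config()) {
  stopifnot(inherits(cfg, "slasso_config"))
  n_sys <- length(systems)
  if (n_sys < cfg$n_train + 1)
    stop("need at least n_train + 1 systems")
  if (any(vapply(systems, function(s) is.na(s$c), logical(1))))
    stop("all systems must have c estimated")
  set.seed(cfg$seed)
  reps <- data.frame(rep = seq_len(cfg$n_rep), lambda_opt = NA_real_,
                     test_sse = NA_real_)
  best <- list(sse = Inf)
  for (r in seq_len(cfg$n_rep)) {
    draw <- sample.int(n_sys, cfg$n_train, replace = TRUE)
    test_idx <- setdiff(seq_len(n_sys), unique(draw))
    stacked <- stack_systems(systems[draw])
    sse_by_lambda <- vapply(cfg$lambda_grid, function(lam) {
      p <- simplex_qp(stacked$A, stacked$y, lambda = lam)
      d <- transit_distribution(p, origin = if (lam == 0) "lasso" else "slasso")
      mean(vapply(systems[test_idx], function(s)
        sse(predict_efflux(s, d), s$L), numeric(1)))
    }, numeric(1))
    j <- which.min(sse_by_lambda)
    reps$lambda_opt[r] <- cfg$lambda_grid[j]
    reps$test_sse[r] <- sse_by_lambda[j]
    if (sse_by_lambda[j] < best$sse) {
      lam <- cfg$lambda_grid[j]
      p <- simplex_qp(stacked$A, stacked$y, lambda = lam)
      best <- list(sse = sse_by_lambda[j], lambda = lam,
                   dist = transit_distribution(
                     p, origin = if (lam == 0) "lasso" else "slasso"))
    }
  }
  list(best_lambda = best$lambda, best_dist = best$dist,
       best_test_sse = best$sse, reps = reps)
}

#' Tail-constraint experiment
#'
#' Quantifies how much of the fit depends on long transit times: for each n,
#' the deconvolution is re-solved with the last n bins pinned to zero
#' (forbidding transits longer than 100 - 2n hours) and, as a control, with
#' n randomly chosen bins pinned to zero. Both fits are trained on the
#' stacked training systems and scored by total SSE on the held-out test
#' systems. The output is the comparison table.
#'
#' @param systems List of `convolution_system`s with `c` estimated.
#' @param n_values Integer vector of tail lengths to constrain (each < 50).
#' @param seed Seed for the random control bins and the train/test split.
#' @param n_test Number of systems held out for testing (default
#'   `min(8, length(systems) - 1)`).
#' @param lambda Smoothing weight used for every fit (default 0).
#' @return Data frame: `n`, `sse_tail_constrained`, `sse_random_constrained`.
#' @export
tail_constraint_test <- function(systems, n_values, seed = 1,
                                 n_test = min(8L, length(systems) - 1L),
                                 lambda = 0) {
  if (any(n_values >= N_BINS)) stop("n must be < ", N_BINS)
  if (any(n_values < 0)) stop("n must be >= 0")
  if (n_test < 1 || n_test >= length(systems))
    stop("n_test must leave at least one training system")
  set.seed(seed)
  test_idx <- sample.int(length(systems), n_test)
  train <- systems[-test_idx]; test <- systems[test_idx]
  stacked <- stack_systems(train)
  total_test_sse <- function(zero_idx) {
    p <- simplex_qp(stacked$A, stacked$y, lambda = lambda, zero_idx = zero_idx)
    d <- transit_distribution(p, origin = "lasso")
    sum(vapply(test, function(s) sse(predict_efflux(s, d), s$L), numeric(1)))
  }
  out <- data.frame(n = n_values, sse_tail_constrained = NA_real_,
                    sse_random_constrained = NA_real_)
  for (i in seq_along(n_values)) {
    n <- n_values[i]
    tail_idx <- if (n > 0) (N_BINS - n + 1L):N_BINS else integer(0)
    rand_idx <- if (n > 0) sample.int(N_BINS, n) else integer(0)
    out$sse_tail_constrained[i] <- total_test_sse(tail_idx)
    out$sse_random_constrained[i] <- total_test_sse(rand_idx)
  }
  out
}
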