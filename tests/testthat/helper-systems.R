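# Shared fixtures, built in code at test time.

# Direct lagged-sum convolution oracle: L_i = sum_j blood(t_i - theta_j) p_j
# with the lag-0 convention blood(0) := first gridded value. Deliberately a
# plain double loop, independent of the matrix construction it checks.
conv_oracle <- function(blood, p) {
  n <- length(blood)
  L <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      lag <- i - j
      b <- if (lag == 0) blood[1] else blood[lag]
      L[i] <- L[i] + b * p[j]
    }
  }
  L
}

# Exhaustive search over the probability simplex on a step grid:
# all compositions of 1/step into `n` parts, scored by ||y - A p||^2
# (+ lambda ||D p||^2). Returns the best grid point.
simplex_grid_search <- function(A, y, step = 0.02, lambda = 0, D = NULL) {
  n <- ncol(A)
  m <- round(1 / step)
  grid <- compositions(m, n) * step
  obj <- colSums((y - A %*% t(grid))^2)
  if (lambda > 0) obj <- obj + lambda * colSums((D %*% t(grid))^2)
  grid[which.min(obj), ]
}

# All compositions of m into n nonnegative parts (rows sum to m).
compositions <- function(m, n) {
  if (n == 1) return(matrix(m, 1, 1))
  do.call(rbind, lapply(0:m, function(k) {
    rest <- compositions(m - k, n - 1)
    cbind(k, rest, deparse.level = 0)
  }))
}

# Build an estimated convolution system from a simulated animal.
sim_to_system <- function(sim, method = "linear") {
  estimate_c(build_convolution_system(interpolate_to_grid(sim$tc, method)))
}

# Small convolution-system stub with arbitrary B and L (bypasses the
# 50-bin container; for exercising the internal QP on toy problems).
toy_system <- function(B, L, c = NA_real_) {
  structure(list(animal_id = "toy", B = B, L = L, c = c),
            class = "convolution_system")
}

# Random point on the simplex.
rsimplex <- function(n) {
  x <- -log(runif(n))
  x / sum(x)
}

# Write a temporary timecourse CSV and return its path.
write_tc_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# Recursive path-enumeration oracle for first-passage probabilities of the
# node walk (vertex 1 reflecting, vertex nv absorbing): probability that
# the walker first reaches nv at exactly step k. Exponential in k; only
# for tiny chains.
fp_enum_oracle <- function(q_fwd, q_bwd, q_stay, nv, k) {
  recurse <- function(pos, steps_left) {
    if (pos == nv) return(if (steps_left == 0) 1 else 0)
    if (steps_left == 0) return(0)
    p_stay <- if (pos == 1) q_stay + q_bwd else q_stay
    p_bwd <- if (pos == 1) 0 else q_bwd
    out <- q_fwd * recurse(pos + 1, steps_left - 1) +
      p_stay * recurse(pos, steps_left - 1)
    if (p_bwd > 0) out <- out + p_bwd * recurse(pos - 1, steps_left - 1)
    out
  }
  recurse(1, k)
}
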