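blood_exp <- function(tau = 7, b0 = 10) b0 * exp(-seq(2, 100, 2) / tau)

grid_system <- function(p_true, c_true = 1, tau = 7) {
  blood <- blood_exp(tau)
  B <- lntransit:::lagged_input_matrix(blood)
  toy_system(B, as.numeric(c_true * (B %*% p_true)))
}

test_that("c estimation is consistent and scale-calibrated", {
  set.seed(3)
  p_true <- rsimplex(50)
  sys <- estimate_c(grid_system(p_true))
  expect_equal(sys$c, 1, tolerance = 1e-4)
  sys25 <- estimate_c(grid_system(p_true, c_true = 2.5))
  expect_equal(sys25$c, 2.5, tolerance = 1e-3 / 2.5)
  expect_error(estimate_c(toy_system(diag(50), rep(0, 50))), "no signal")
})

test_that("simplex LASSO identifies a point mass and satisfies constraints", {
  p_true <- numeric(50); p_true[10] <- 1
  sys <- estimate_c(grid_system(p_true))
  d <- solve_lasso(sys)
  expect_gte(d$p[10], 0.99)
  expect_equal(sum(d$p), 1, tolerance = 1e-6)
  expect_gte(min(d$p), 0)

  # constraint satisfaction on generic noisy systems
  set.seed(11)
  for (i in 1:5) {
    sysn <- grid_system(rsimplex(50))
    sysn$L <- pmax(sysn$L + rnorm(50, 0, 0.05), 0)
    dn <- solve_lasso(estimate_c(sysn))
    expect_equal(sum(dn$p), 1, tolerance = 1e-6)
    expect_gte(min(dn$p), 0)
  }
})

test_that("toy-system solution matches exhaustive simplex-grid search", {
  # 5-bin system, hand-specified input and noisy efflux
  B <- lntransit:::lagged_input_matrix(c(3, 2.2, 1.6, 1.1, 0.8))
  p_true <- c(0.1, 0.45, 0.25, 0.15, 0.05)
  set.seed(5)
  y <- as.numeric(B %*% p_true) + rnorm(5, 0, 0.1)
  p_qp <- lntransit:::simplex_qp(B, y)
  p_grid <- simplex_grid_search(B, y, step = 0.02)
  expect_lt(max(abs(p_qp - p_grid)), 0.02)        # within grid resolution
  expect_lte(sum((y - B %*% p_qp)^2), sum((y - B %*% p_grid)^2) + 1e-10)

  # with a smoothing penalty too
  D <- lntransit:::second_difference_operator(5)
  p_qp_s <- lntransit:::simplex_qp(B, y, lambda = 2, D = D)
  p_grid_s <- simplex_grid_search(B, y, step = 0.02, lambda = 2, D = D)
  expect_lt(max(abs(p_qp_s - p_grid_s)), 0.02)
})

test_that("S-LASSO reduces to LASSO at lambda 0 and flattens at huge lambda", {
  set.seed(9)
  sys <- estimate_c(grid_system(rsimplex(50)))
  d0 <- solve_lasso(sys)
  d0b <- solve_slasso(sys, 0)
  expect_lt(max(abs(d0$p - d0b$p)), 1e-8)

  dbig <- solve_slasso(sys, 1e8)
  D <- lntransit:::second_difference_operator(50)
  expect_lt(sum((D %*% dbig$p)^2), 1e-6)
  expect_error(solve_slasso(sys, -1), "nonnegative")
})

test_that("training SSE is non-increasing as lambda decreases", {
  set.seed(13)
  sys <- grid_system(rsimplex(50))
  sys$L <- pmax(sys$L + rnorm(50, 0, 0.1), 0)
  sys <- estimate_c(sys)
  lams <- c(0, 1, 5, 20, 100, 1000)
  train_sse <- vapply(lams, function(l)
    sse(predict_efflux(sys, solve_slasso(sys, l)), sys$L), numeric(1))
  expect_true(all(diff(train_sse) >= -1e-8))
})

test_that("held-out error is minimised at intermediate smoothing", {
  # one noisy training animal, one clean held-out animal, bimodal truth
  fam <- list(w = 0.6, mu1 = 14, lam1 = 200, mu2 = 60, lam2 = 2000)
  train <- sim_to_system(simulate_open_loop(truth_spec(
    "mixture_of_two", fam, blood_tau = 7, schedule = "cannulation",
    noise = "gaussian_multiplicative", noise_param = 0.10, seed = 1)))
  test <- sim_to_system(simulate_open_loop(truth_spec(
    "mixture_of_two", fam, blood_tau = 7, schedule = "uniform_2h",
    noise = "none")))
  test_sse <- function(lam)
    sse(predict_efflux(test, solve_slasso(train, lam)), test$L)
  coarse <- vapply(c(0, 10, 100), test_sse, numeric(1))
  expect_lt(coarse[2], coarse[1])
  expect_lt(coarse[2], coarse[3])
  # fine-grid check: the interior optimum is real, not a grid artifact
  lams <- c(0, 2, 5, 10, 20, 50, 100)
  fine <- vapply(lams, test_sse, numeric(1))
  best <- which.min(fine)
  expect_true(best > 1 && best < length(lams))
})

test_that("predicted efflux equals c B p and the lagged-sum oracle", {
  set.seed(17)
  blood <- blood_exp()
  sys <- estimate_c(grid_system(rsimplex(50), c_true = 2))
  # basis vector: column extraction
  for (j in c(1, 25, 50)) {
    p <- numeric(50); p[j] <- 1
    d <- transit_distribution(p, "truth")
    expect_equal(predict_efflux(sys, d), sys$c * sys$B[, j])
  }
  # round trip and oracle
  p_true <- rsimplex(50)
  sys2 <- estimate_c(grid_system(p_true, c_true = 1.7))
  d2 <- transit_distribution(p_true, "truth")
  expect_equal(predict_efflux(sys2, d2), sys2$L, tolerance = 1e-6)
  expect_equal(predict_efflux(sys2, d2),
               sys2$c * conv_oracle(blood, p_true), tolerance = 1e-8)
})

test_that("transit summaries follow the bin-edge conventions", {
  p <- numeric(50); p[10] <- 1   # point mass at 20 h
  d <- transit_distribution(p, "truth")
  expect_equal(transit_summary(d), list(median_h = 20, mean_h = 20))

  u <- transit_distribution(rep(1 / 50, 50), "truth")
  expect_equal(transit_summary(u)$mean_h, 51)  # sum(2j)/50

  p2 <- numeric(50); p2[5] <- 0.5; p2[15] <- 0.5  # 10 h and 30 h
  d2 <- transit_distribution(p2, "truth")
  expect_equal(transit_summary(d2), list(median_h = 10, mean_h = 20))
})

test_that("cross-animal summaries take the median of means", {
  expect_equal(summarize_across(c(10, 20, 30)), 20)
  expect_equal(summarize_across(rep(25, 5)), 25)
  expect_error(summarize_across(numeric(0)), "empty")
  sums <- lapply(c(10, 30), function(h) {
    p <- numeric(50); p[h / 2] <- 1
    transit_summary(transit_distribution(p, "truth"))
  })
  expect_equal(summarize_across(sums), 20)
})

test_that("piecewise confidence band implements mean +/- 1.96 SEM", {
  p <- rsimplex(50)
  same <- lapply(1:4, function(i) transit_distribution(p, "truth"))
  ci <- piecewise_ci(same)
  expect_equal(ci$lower, ci$upper)          # zero-width at zero variance
  expect_equal(ci$mean, p)

  # hand evaluation on a constructed triplet: bin 1 values 0.1, 0.2, 0.3
  mk <- function(v) transit_distribution(c(v, rep((1 - v) / 49, 49)), "truth")
  ci3 <- piecewise_ci(lapply(c(0.1, 0.2, 0.3), mk))
  expect_equal(ci3$mean[1], 0.2)
  expect_equal(ci3$upper[1], 0.2 + 1.96 * 0.1 / sqrt(3), tolerance = 1e-12)
  expect_equal(ci3$lower[1], 0.2 - 1.96 * 0.1 / sqrt(3), tolerance = 1e-12)

  set.seed(19)
  rand <- lapply(1:6, function(i) transit_distribution(rsimplex(50), "truth"))
  cir <- piecewise_ci(rand)
  expect_true(all(cir$lower <= cir$mean & cir$mean <= cir$upper))
  expect_error(piecewise_ci(rand[1]), "at least 2")
})

test_that("resampled tuning recovers a shared truth and is reproducible", {
  spec <- truth_spec("inverse_gaussian", list(mu = 30, lam = 60),
                     blood_tau = 7, schedule = "uniform_2h", noise = "none")
  sims <- simulate_cohort(spec, 12, seed = 3)
  systems <- lapply(sims, sim_to_system)
  cfg <- slasso_config(lambda_grid = c(0, 10), n_train = 3, n_rep = 10,
                       seed = 4)
  tun <- concat_and_tune(systems, cfg)
  expect_equal(tun$best_lambda, 0)     # noise-free: no smoothing needed
  expect_lt(sqrt(sum((tun$best_dist$p - sims[[1]]$truth$p)^2)), 1e-3)
  expect_equal(nrow(tun$reps), 10)

  tun2 <- concat_and_tune(systems, cfg)
  expect_identical(tun$reps, tun2$reps)  # same seed, same draws
  expect_error(concat_and_tune(systems[1:3], cfg), "n_train")
})

test_that("pinning tail bins degrades the fit of a long-tailed truth", {
  fam <- list(w = 0.65, mu1 = 20, lam1 = 100, mu2 = 85, lam2 = 6000)
  spec <- truth_spec("mixture_of_two", fam, blood_tau = 7,
                     schedule = "uniform_2h", noise = "none")
  expect_gt(sum(make_truth(spec)$p[seq(2, 100, 2) > 70]), 0.3)
  sims <- simulate_cohort(spec, 10, seed = 9)
  systems <- lapply(sims, sim_to_system)
  tt <- tail_constraint_test(systems, n_values = c(0, 15), seed = 2,
                             n_test = 4)
  expect_equal(tt$sse_tail_constrained[1], tt$sse_random_constrained[1])
  expect_gt(tt$sse_tail_constrained[2], tt$sse_tail_constrained[1])
  # seeded control column is reproducible
  tt2 <- tail_constraint_test(systems, n_values = c(0, 15), seed = 2,
                              n_test = 4)
  expect_identical(tt, tt2)
  expect_error(tail_constraint_test(systems, n_values = 50), "< 50")
})
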