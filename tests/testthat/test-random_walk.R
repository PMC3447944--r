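test_that("transition matrix has the documented boundary behaviour", {
  P <- build_transition_matrix(mc_params(1, 0, n_vertices = 2, dt_min = 1))
  expect_equal(P, matrix(c(0, 0, 1, 1), 2, 2))

  P3 <- build_transition_matrix(mc_params(0.5, 0, n_vertices = 3, dt_min = 1))
  expect_equal(P3, matrix(c(0.5, 0, 0, 0.5, 0.5, 0, 0, 0.5, 1), 3, 3))

  set.seed(2)
  for (i in 1:10) {
    q <- rsimplex(3)
    if (q[1] == 0) next
    P <- build_transition_matrix(mc_params(q[1], q[2], q[3],
                                           n_vertices = sample(2:30, 1),
                                           dt_min = 1))
    expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  }
  expect_error(mc_params(0.5, 0.6, 0.2, n_vertices = 5, dt_min = 1), "sum")
  expect_error(mc_params(0, 0.5, 0.5, n_vertices = 5, dt_min = 1), "positive")
})

test_that("first-passage law matches closed form and path enumeration", {
  # deterministic hop
  law1 <- first_passage_distribution(
    build_transition_matrix(mc_params(1, 0, n_vertices = 2, dt_min = 1)), 5)
  expect_equal(law1$f, c(1, 0, 0, 0, 0))
  expect_equal(law1$tail_mass, 0)

  # n = 3, (0.5, 0, 0.5): f_k = (k-1) 0.5^k, exact
  P <- build_transition_matrix(mc_params(0.5, 0, n_vertices = 3, dt_min = 60))
  law <- first_passage_distribution(P, 12, dt_min = 60)
  k <- 2:12
  expect_lt(max(abs(law$f[k] - (k - 1) * 0.5^k)), 1e-12)
  expect_equal(law$f[1], 0)

  # general small chain vs recursive path enumeration
  for (k in 1:9) {
    expect_equal(law$f[k], fp_enum_oracle(0.5, 0, 0.5, 3, k),
                 tolerance = 1e-12)
  }
  pq <- c(0.4, 0.25, 0.35)
  P4 <- build_transition_matrix(mc_params(pq[1], pq[2], pq[3],
                                          n_vertices = 4, dt_min = 1))
  law4 <- first_passage_distribution(P4, 10)
  for (k in 1:10) {
    expect_equal(law4$f[k], fp_enum_oracle(pq[1], pq[2], pq[3], 4, k),
                 tolerance = 1e-12)
  }
  expect_error(first_passage_distribution(P4, 0), "k_max")
})

test_that("tridiagonal and dense propagation agree", {
  for (nv in c(2, 5, 17)) {
    pm <- mc_params(0.3, 0.25, n_vertices = nv, dt_min = 5)
    dense <- first_passage_distribution(build_transition_matrix(pm), 500)
    tri <- lntransit:::fp_law_params(pm, 500)
    expect_equal(dense$f, tri$f, tolerance = 1e-12)
    expect_equal(dense$tail_mass, tri$tail_mass, tolerance = 1e-12)
  }
})

test_that("first-passage law matches Monte-Carlo walkers", {
  pm <- mc_params(0.3, 0.3, n_vertices = 10, dt_min = 10)
  n_walk <- 1e5
  w <- simulate_walkers(pm, n_walkers = n_walk, k_max = 5000, seed = 7)
  law <- first_passage_distribution(build_transition_matrix(pm), 5000,
                                    dt_min = 10)
  emp_law <- structure(list(f = tabulate(w$steps, nbins = 5000) / n_walk,
                            dt_min = 10, tail_mass = w$n_censored / n_walk),
                       class = "first_passage_law")
  emp <- bin_to_hours(emp_law)$p
  thr <- bin_to_hours(law)$p
  se <- sqrt(thr * (1 - thr) / n_walk)
  expect_lt(max(abs(emp - thr) / pmax(se, 1e-12)), 3)
})

test_that("conservation: f is nonnegative with non-decreasing arrivals", {
  set.seed(23)
  for (i in 1:5) {
    q <- rsimplex(3)
    if (q[1] < 0.05) q <- c(0.3, q[2], 0.7 - q[2])
    pm <- mc_params(q[1], q[2], 1 - q[1] - q[2],
                    n_vertices = sample(3:15, 1), dt_min = 5)
    law <- lntransit:::fp_law_params(pm, 2000)
    expect_true(all(law$f >= -1e-15))
    expect_true(all(diff(cumsum(law$f)) >= -1e-15))
    expect_equal(sum(law$f) + law$tail_mass, 1, tolerance = 1e-9)
  }
})

test_that("binning to hours respects half-open edges and conserves mass", {
  mk_law <- function(f, dt, tail = 1 - sum(f))
    structure(list(f = f, dt_min = dt, tail_mass = tail),
              class = "first_passage_law")
  # all mass at k = 2 with dt = 60 min lands in (0, 2] h
  d <- bin_to_hours(mk_law(c(0, 1), 60))
  expect_equal(d$p[1], 1)
  # dt = 1 min: k = 119 -> (0,2]; k = 121 -> (2,4]
  f <- numeric(121); f[119] <- 0.5; f[121] <- 0.5
  d2 <- bin_to_hours(mk_law(f, 1))
  expect_equal(d2$p[1:2], c(0.5, 0.5))
  # random law conserves mass including the beyond-100h tail
  set.seed(29)
  f3 <- rsimplex(4000) * 0.9
  d3 <- bin_to_hours(mk_law(f3, 2, tail = 0.1))
  expect_equal(sum(d3$p) + d3$tail_mass, 1, tolerance = 1e-9)
})

test_that("law mean matches the mean of the binned distribution", {
  pm <- mc_params(0.35, 0.3, n_vertices = 8, dt_min = 5)
  law <- lntransit:::fp_law_params(pm, 50000)
  expect_lt(law$tail_mass, 1e-6)
  d <- bin_to_hours(law)
  expect_lt(abs(mean_first_passage_h(law) - transit_summary(d)$mean_h), 2)
})

test_that("grid-search fit recovers generating parameters", {
  pm <- mc_params(0.3, 0.3, n_vertices = 10, dt_min = 5)
  spec <- truth_spec("mc", pm, blood_tau = 7, schedule = "uniform_2h",
                     noise = "none")
  systems <- lapply(simulate_cohort(spec, 2, seed = 5), sim_to_system)
  # reduced stage-1 grid bracketing the truth (keeps the search quick)
  fit <- fit_mc(systems, q_stay_grid = c(0.2, 0.4, 0.6),
                ratio_grid = c(0.5, 1, 2), n_grid = c(5, 10, 20),
                dt_grid = c(5, 10))
  expect_equal(fit$params$n_vertices, 10L)
  expect_equal(fit$params$dt_min, 5)
  expect_equal(fit$params$q_fwd, 0.3, tolerance = 1e-9)
  expect_equal(fit$params$q_bwd, 0.3, tolerance = 1e-9)
  expect_lt(fit$sse, 1e-4)
  # surface covers the stage-1 (q_stay x ratio) plane at the optimum n, dt
  expect_equal(nrow(fit$surface), 9)
  expect_error(fit_mc(systems, q_stay_grid = numeric(0)), "empty grid")
})

test_that("a two-point grid returns the lower-SSE grid point", {
  pm <- mc_params(0.3, 0.3, n_vertices = 10, dt_min = 5)
  spec <- truth_spec("mc", pm, blood_tau = 7, schedule = "uniform_2h",
                     noise = "none")
  systems <- lapply(simulate_cohort(spec, 1, seed = 6), sim_to_system)
  fit <- fit_mc(systems, q_stay_grid = 0.4, ratio_grid = 1,
                n_grid = c(10, 40), dt_grid = 5, refine_step = 0.1)
  s1 <- fit$stage1
  expect_equal(fit$params$n_vertices,
               as.integer(s1$n[which.min(s1$sse)]))
})

test_that("reinjection steady state solves pi P' = pi with declining occupancy", {
  # symmetric two-state example
  occ2 <- steady_state_occupancy(mc_params(0.5, 0, n_vertices = 2, dt_min = 1))
  expect_equal(as.numeric(occ2), c(0.5, 0.5))
  expect_equal(attr(occ2, "P"), matrix(0.5, 2, 2))

  occ5 <- steady_state_occupancy(mc_params(0.3, 0.3, n_vertices = 5,
                                           dt_min = 1))
  P5 <- attr(occ5, "P")
  expect_lt(max(abs(as.numeric(occ5 %*% P5) - as.numeric(occ5))), 1e-10)
  expect_equal(sum(occ5), 1)
  expect_true(all(diff(as.numeric(occ5)) <= 1e-12))  # declines towards exit

  # independent linear-solve oracle via eigen decomposition
  ev <- eigen(t(P5))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  expect_equal(as.numeric(occ5), stat, tolerance = 1e-10)

  # fixed-point residual across random parameter draws
  set.seed(31)
  for (i in 1:5) {
    q <- rsimplex(3)
    if (q[1] < 0.05) next
    occ <- steady_state_occupancy(mc_params(q[1], q[2], 1 - q[1] - q[2],
                                            n_vertices = sample(3:20, 1),
                                            dt_min = 1))
    expect_lt(max(abs(as.numeric(occ %*% attr(occ, "P")) - as.numeric(occ))),
              1e-10)
  }
})
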