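# Continuous transit-time laws. The inverse Gaussian is the exact first-
# passage law of one-dimensional Brownian motion with positive drift: with
# unit diffusion, barrier distance d and drift v, the passage time is
# IG(mu = d / v, lambda = d^2). The Gaussian comparator models directed,
# synchronised migration and is intentionally naive.

#' Inverse-Gaussian parameters
#'
#' @param mu Mean transit time in hours (> 0).
#' @param lam Shape parameter in hours (> 0). In the Brownian drift form
#'   (distance d, drift v, unit variance): mu = d/v and lam = d^2, so
#'   d = sqrt(lam) and v = sqrt(lam)/mu.
#' @return A list of class `ig_params` (with derived `d` and `v`).
#' @export
ig_params <- function(mu, lam) {
  if (mu <= 0 || lam <= 0) stop("mu and lam must be positive")
  structure(list(mu = mu, lam = lam, d = sqrt(lam), v = sqrt(lam) / mu),
            class = "ig_params")
}

#' Gaussian transit-time parameters
#' @param mean_h Mean in hours.
#' @param sd_h Standard deviation in hours (> 0).
#' @return A list of class `gauss_params`.
#' @export
gauss_params <- function(mean_h, sd_h) {
  if (sd_h <= 0) stop("sd_h must be positive")
  structure(list(mean_h = mean_h, sd_h = sd_h), class = "gauss_params")
}

#' Inverse-Gaussian density
#'
#' sqrt(lam / (2 pi t^3)) exp(-lam (t - mu)^2 / (2 mu^2 t)) for t > 0;
#' zero for t <= 0 (the support is the positive reals).
#'
#' @param t Time(s) in hours; vectorised.
#' @param params An [ig_params()].
#' @return Density per hour.
#' @export
inverse_gaussian_pdf <- function(t, params) {
  stopifnot(inherits(params, "ig_params"))
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- sqrt(params$lam / (2 * pi * tp^3)) *
    exp(-params$lam * (tp - params$mu)^2 / (2 * params$mu^2 * tp))
  out
}

#' Inverse-Gaussian cumulative distribution function
#'
#' Standard closed form via the normal CDF.
#'
#' @inheritParams inverse_gaussian_pdf
#' @return P(T <= t).
#' @export
inverse_gaussian_cdf <- function(t, params) {
  stopifnot(inherits(params, "ig_params"))
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  a <- sqrt(params$lam / tp)
  out[pos] <- pnorm(a * (tp / params$mu - 1)) +
    exp(2 * params$lam / params$mu + pnorm(-a * (tp / params$mu + 1),
                                           log.p = TRUE))
  pmin(pmax(out, 0), 1)
}

#' Gaussian transit-time density
#' @param t Time(s) in hours; vectorised.
#' @param params A [gauss_params()].
#' @return Density per hour.
#' @export
gaussian_pdf <- function(t, params) {
  stopifnot(inherits(params, "gauss_params"))
  dnorm(t, mean = params$mean_h, sd = params$sd_h)
}

#' Discretise a continuous density onto the 2-hour bins
#'
#' Each bin probability is the integral of the density over (theta - 2,
#' theta]; mass outside (0, 100] (including any negative-time Gaussian
#' mass) is recorded as `tail_mass` and never renormalised away. If a CDF
#' is supplied the bin masses are exact differences; otherwise each bin is
#' integrated by adaptive quadrature.
#'
#' @param pdf Function of time in hours returning the density.
#' @param cdf Optional CDF function; used instead of quadrature if given.
#' @param origin Origin label for the result.
#' @return A [transit_distribution()].
#' @export
discretize_density <- function(pdf, cdf = NULL, origin = "truth") {
  edges <- c(0, GRID_H)
  if (!is.null(cdf)) {
    cm <- cdf(edges)
    p <- diff(cm)
  } else {
    p <- vapply(seq_len(N_BINS), function(j)
      integrate(pdf, edges[j], edges[j + 1], rel.tol = 1e-10,
                abs.tol = 1e-12)$value, numeric(1))
  }
  p <- pmax(p, 0)
  tail_mass <- max(1 - sum(p), 0)
  transit_distribution(p, origin = origin, tail_mass = tail_mass)
}

# Bin masses for each family via exact CDF differences (fit hot path).
binned_family <- function(family, par1, par2) {
  if (family == "inverse_gaussian") {
    pr <- ig_params(par1, par2)
    discretize_density(function(t) inverse_gaussian_pdf(t, pr),
                       cdf = function(t) inverse_gaussian_cdf(t, pr),
                       origin = "inverse_gaussian")
  } else if (family == "gaussian") {
    pr <- gauss_params(par1, par2)
    discretize_density(function(t) gaussian_pdf(t, pr),
                       cdf = function(t) pnorm(t, par1, par2),
                       origin = "gaussian")
  } else stop("unknown family: ", family)
}

#' Fit a continuous transit-time model to efflux data
#'
#' Minimises the total training SSE of predicted efflux c B p(params)
#' against L, where p is the discretised density. Deterministic multi-start
#' bounded optimisation: a coarse parameter grid of starts, each refined by
#' Nelder-Mead on log-parameters.
#'
#' @param systems Training list of `convolution_system`s with `c` estimated.
#' @param family `"inverse_gaussian"` or `"gaussian"`.
#' @param test_systems Optional held-out systems on which per-system SSE is
#'   reported.
#' @param starts Optional data frame of starting values (columns par1,
#'   par2). Defaults: IG mu in {10,...,60} x lam in {10, 50, 100, 500,
#'   1000}; Gaussian mean in {10,...,60} x sd in {5, 10, 20, 40}.
#' @return A list of class `fit_result`: `model`, `params`, `dist`,
#'   `train_sse`, `test_sse` (named per-system vector or NULL).
#' @export
fit_continuous <- function(systems, family = c("inverse_gaussian", "gaussian"),
                           test_systems = NULL, starts = NULL) {
  family <- match.arg(family)
  if (length(systems) < 1) stop("need at least one training system")
  if (any(vapply(systems, function(s) is.na(s$c), logical(1))))
    stop("all systems must have c estimated")
  if (is.null(starts)) {
    starts <- if (family == "inverse_gaussian")
      expand.grid(par1 = seq(10, 60, by = 10),
                  par2 = c(10, 50, 100, 500, 1000))
    else
      expand.grid(par1 = seq(10, 60, by = 10), par2 = c(5, 10, 20, 40))
  }
  obj <- function(logpar) {
    d <- binned_family(family, exp(logpar[1]), exp(logpar[2]))
    sum(vapply(systems, function(s) sse(predict_efflux(s, d), s$L),
               numeric(1)))
  }
  best <- list(value = Inf)
  for (i in seq_len(nrow(starts))) {
    r <- tryCatch(
      optim(log(c(starts$par1[i], starts$par2[i])), obj,
            method = "Nelder-Mead",
            control = list(reltol = 1e-10, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(r) && r$value < best$value) best <- r
  }
  if (!is.finite(best$value)) stop("no start converged")
  par <- exp(best$par)
  params <- if (family == "inverse_gaussian") ig_params(par[1], par[2])
            else gauss_params(par[1], par[2])
  d <- binned_family(family, par[1], par[2])
  test_sse <- NULL
  if (!is.null(test_systems)) {
    test_sse <- vapply(test_systems, function(s)
      sse(predict_efflux(s, d), s$L), numeric(1))
    names(test_sse) <- vapply(test_systems, function(s)
      as.character(s$animal_id), character(1))
  }
  structure(list(model = family, params = params, dist = d,
                 train_sse = best$value, test_sse = test_sse),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: train SSE %.4g", x$model, x$train_sse))
  if (!is.null(x$test_sse))
    cat(sprintf(", mean test SSE %.4g", mean(x$test_sse)))
  cat("\n")
  invisible(x)
}
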