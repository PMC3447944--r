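#' Fit the early exponential decay of labelled cells in blood
#'
#' Labelled lymphocytes leave blood (mainly by trans-endothelial migration
#' into lymph nodes) at a rate proportional to their concentration, so over
#' the first few hours the blood percentage follows B(t) = B0 exp(-t/tau).
#' Only observations within the fitting window are used, because cells that
#' complete a nodal transit start returning to blood after ~8 hours. The
#' default fit is nonlinear least squares on the raw percent scale,
#' initialised from the log-linear regression (which makes the optimisation
#' deterministic); `scale = "log"` returns the log-linear fit itself.
#'
#' @param tc A [timecourse()].
#' @param window_h Fitting window in hours (default 8).
#' @param scale `"raw"` (default) or `"log"`.
#' @return An object of class `blood_fit`: `b0` (percent at t = 0), `tau`
#'   (mean lifetime in blood, hours), `window_h`, `sse`, `n_obs`.
#' @export
fit_exponential <- function(tc, window_h = 8, scale = c("raw", "log")) {
  if (!inherits(tc, "timecourse")) stop("tc must be a timecourse")
  scale <- match.arg(scale)
  keep <- !is.na(tc$pct_blood) & tc$time_h <= window_h
  t <- tc$time_h[keep]; y <- tc$pct_blood[keep]
  if (length(t) < 3)
    stop("need at least 3 blood observations within the window")
  if (any(y <= 0))
    stop("blood percentages in the window must be positive")

  ll <- lm(log(y) ~ t)
  b0_init <- exp(coef(ll)[[1]])
  slope <- coef(ll)[[2]]
  tau_init <- if (slope < 0) -1 / slope else window_h

  if (scale == "log") {
    if (slope >= 0) stop("log-linear fit has non-negative slope")
    b0 <- b0_init; tau <- tau_init
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b0 * exp(-t / tau),
                        start = list(b0 = b0_init, tau = tau_init),
                        lower = c(b0 = 0, tau = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("exponential fit did not converge: ",
                               conditionMessage(e)))
    b0 <- coef(fit)[["b0"]]; tau <- coef(fit)[["tau"]]
  }
  sse <- sum((y - b0 * exp(-t / tau))^2)
  stopifnot(tau > 0, b0 >= 0)
  structure(list(animal_id = tc$animal_id, b0 = b0, tau = tau,
                 window_h = window_h, sse = sse, n_obs = length(t),
                 scale = scale),
            class = "blood_fit")
}

#' @export
print.blood_fit <- function(x, ...) {
  cat(sprintf("<blood_fit> %s: B0 = %.3g%%, mean lifetime tau = %.3g h (%d obs <= %g h)\n",
              x$animal_id, x$b0, x$tau, x$n_obs, x$window_h))
  invisible(x)
}

#' Summarise mean blood lifetimes across animals
#'
#' @param fits A list of `blood_fit` objects, or a numeric vector of mean
#'   lifetimes (hours).
#' @return A list with `median_h` and `mean_h`. The median uses the
#'   midpoint-of-two rule for even n.
#' @export
summarize_lifetimes <- function(fits) {
  taus <- if (is.numeric(fits)) fits
          else vapply(fits, function(f) f$tau, numeric(1))
  if (length(taus) == 0) stop("empty list of fits")
  list(median_h = median(taus), mean_h = mean(taus))
}
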