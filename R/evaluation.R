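#' Sum of squared errors between predicted and observed efflux
#'
#' @param pred,obs Numeric vectors of equal length (percent scale).
#' @return Scalar SSE.
#' @export
sse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  sum((pred - obs)^2)
}

#' Compare transit-time models on a train/test split
#'
#' Fits every requested model on the training systems and reports the SSE
#' of its predicted efflux on each test system (each with its own c), plus
#' per-model means — the model-comparison table. Models: `"lasso"` (simplex
#' LASSO on the stacked training systems), `"slasso"` (smoothing tuned by
#' [concat_and_tune()]), `"mc"` ([fit_mc()]), `"inverse_gaussian"` and
#' `"gaussian"` ([fit_continuous()]). A model failure is recorded as
#' missing, not fatal.
#'
#' @param systems Named list of `convolution_system`s with `c` estimated.
#' @param train_idx,test_idx Disjoint index vectors into `systems`.
#' @param models Character vector of model names (default all five).
#' @param seed Seed for the S-LASSO resampling.
#' @param mc_args,slasso_args Optional lists of extra arguments passed to
#'   [fit_mc()] / [slasso_config()].
#' @return A list of class `model_comparison`: `table` (data frame,
#'   system_id x model SSEs), `mean_sse` (named vector), `fits` (per-model
#'   details).
#' @export
compare_models <- function(systems, train_idx, test_idx,
                           models = c("lasso", "slasso", "mc",
                                      "inverse_gaussian", "gaussian"),
                           seed = 1, mc_args = list(), slasso_args = list()) {
  if (length(intersect(train_idx, test_idx)))
    stop("train and test sets must be disjoint")
  train <- systems[train_idx]; test <- systems[test_idx]
  if (!length(train) || !length(test)) stop("empty train or test set")

  dist_for <- function(model) {
    switch(model,
      lasso = {
        stacked <- stack_systems(train)
        transit_distribution(simplex_qp(stacked$A, stacked$y),
                             origin = "lasso")
      },
      slasso = {
        cfg <- do.call(slasso_config, c(
          list(n_train = max(1L, length(train) - 1L), seed = seed),
          slasso_args))
        concat_and_tune(train, cfg)$best_dist
      },
      mc = do.call(fit_mc, c(list(train), mc_args))$dist,
      inverse_gaussian = fit_continuous(train, "inverse_gaussian")$dist,
      gaussian = fit_continuous(train, "gaussian")$dist,
      stop("unknown model: ", model))
  }

  ids <- vapply(test, function(s) as.character(s$animal_id), character(1))
  tab <- data.frame(system_id = ids)
  fits <- list()
  for (m in models) {
    d <- tryCatch(dist_for(m), error = function(e) NULL)
    fits[[m]] <- d
    tab[[m]] <- if (is.null(d)) NA_real_ else
      vapply(test, function(s) sse(predict_efflux(s, d), s$L), numeric(1))
  }
  mean_sse <- vapply(models, function(m) mean(tab[[m]]), numeric(1))
  structure(list(table = tab, mean_sse = mean_sse, fits = fits),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> mean test SSE per model:\n")
  print(round(x$mean_sse, 4))
  invisible(x)
}
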