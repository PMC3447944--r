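# Published per-animal summaries from seventeen long-term sheep lymph-node
# cannulation experiments (prescapular and popliteal nodes). The raw time
# courses were never deposited; these summary tables are the only numeric
# record of the experiments and serve as reference inputs for the
# cross-animal summary statistics.

#' Reference per-sheep mean blood lifetimes
#'
#' Mean lifetime of labelled T cells in blood before trans-endothelial
#' migration, from exponential fits to the first eight hours post infusion,
#' for seventeen cannulations.
#'
#' @return Data frame with columns `animal_id`, `mean_lifetime_h`.
#' @export
sheep_blood_lifetimes <- function() {
  read.csv(system.file("extdata", "sheep_blood_lifetimes.csv",
                       package = "lntransit"))
}

#' Reference per-sheep transit-time summaries
#'
#' Median and mean nodal migration times (hours) and deconvolution fit SSE
#' for seventeen cannulations.
#'
#' @return Data frame with columns `animal_id`, `median_h`, `mean_h`, `sse`.
#' @export
sheep_transit_summaries <- function() {
  read.csv(system.file("extdata", "sheep_transit_summaries.csv",
                       package = "lntransit"))
}

#' Reference held-out model-comparison SSEs
#'
#' Test-set SSE of predicted versus observed efflux for the empirical LASSO
#' distribution, the discrete random-walk model, the inverse Gaussian and
#' the Gaussian, on eight held-out cannulations.
#'
#' @return Data frame with one row per test animal and one SSE column per
#'   model.
#' @export
sheep_model_test_sse <- function() {
  read.csv(system.file("extdata", "sheep_model_test_sse.csv",
                       package = "lntransit"))
}
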