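#' Construct a cannulation time course
#'
#' One animal's irregular samples of the percentage of labelled cells in
#' blood and in efferent lymph. Times must be strictly increasing;
#' per-channel missing values (`NA`) are allowed, but each channel needs at
#' least two usable observations within the first 100 h.
#'
#' @param animal_id Character label for the animal/cannulation.
#' @param time_h Numeric vector of sampling times in hours (>= 0).
#' @param pct_blood,pct_lymph Percent labelled cells in each channel
#'   (>= 0, `NA` allowed).
#' @return An object of class `timecourse`.
#' @export
timecourse <- function(animal_id, time_h, pct_blood, pct_lymph) {
  stopifnot(length(time_h) == length(pct_blood),
            length(time_h) == length(pct_lymph))
  if (!is.numeric(time_h) || !is.numeric(pct_blood) || !is.numeric(pct_lymph))
    stop("time_h, pct_blood and pct_lymph must be numeric")
  ord <- order(time_h)
  time_h <- time_h[ord]; pct_blood <- pct_blood[ord]; pct_lymph <- pct_lymph[ord]
  if (anyNA(time_h)) stop("missing sampling times")
  if (any(diff(time_h) == 0)) stop("duplicate time points in time course")
  if (any(time_h < 0)) stop("negative sampling times")
  if (any(pct_blood < 0, na.rm = TRUE) || any(pct_lymph < 0, na.rm = TRUE))
    stop("negative percentages")
  for (ch in c("pct_blood", "pct_lymph")) {
    v <- get(ch)
    if (sum(!is.na(v) & time_h <= 100) < 2)
      stop("fewer than 2 usable observations in channel ", ch)
  }
  structure(list(animal_id = as.character(animal_id),
                 time_h = time_h, pct_blood = pct_blood,
                 pct_lymph = pct_lymph),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat("<timecourse> animal", x$animal_id, "-", length(x$time_h),
      "samples over", round(max(x$time_h), 1), "h\n")
  invisible(x)
}

#' Read a time-course CSV
#'
#' Expects a comma-separated file with header `time_h,pct_blood,pct_lymph`
#' ('.' decimal, UTF-8). Rows are sorted by time; duplicate times, negative
#' percentages and channels with fewer than two usable points are errors.
#'
#' @param path Path to the CSV file.
#' @param animal_id Label for the animal; defaults to the file base name.
#' @return A [timecourse()].
#' @export
read_timecourse <- function(path, animal_id = NULL) {
  d <- read.csv(path, header = TRUE)
  need <- c("time_h", "pct_blood", "pct_lymph")
  if (!all(need %in% names(d)))
    stop("file must have columns time_h, pct_blood, pct_lymph")
  if (is.null(animal_id))
    animal_id <- sub("\\.[^.]*$", "", basename(path))
  timecourse(animal_id, d$time_h, d$pct_blood, d$pct_lymph)
}

#' Write a time course to CSV
#' @param tc A [timecourse()].
#' @param path Output path.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.timecourse <- function(x, ...) {
  data.frame(time_h = x$time_h, pct_blood = x$pct_blood,
             pct_lymph = x$pct_lymph)
}

#' Read a manifest of per-animal time-course files
#'
#' The manifest is a CSV with columns `animal_id,path`; relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return Named list of [timecourse()] objects.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, header = TRUE)
  if (!all(c("animal_id", "path") %in% names(m)))
    stop("manifest must have columns animal_id, path")
  base <- dirname(path)
  out <- lapply(seq_len(nrow(m)), function(i) {
    f <- m$path[i]
    if (!file.exists(f)) f <- file.path(base, f)
    read_timecourse(f, animal_id = m$animal_id[i])
  })
  names(out) <- m$animal_id
  out
}

# Interpolate one irregular channel onto the grid. Outside the observed
# range the series is extended flat (first/last observed value); negative
# spline interpolants are clipped to zero since values are percentages.
interp_channel <- function(time_h, values, grid, method) {
  keep <- !is.na(values)
  t <- time_h[keep]; v <- values[keep]
  if (length(t) < 2) stop("fewer than 2 usable observations to interpolate")
  out <- switch(method,
    linear = approx(t, v, xout = grid, rule = 2)$y,
    cubic_spline = {
      f <- splinefun(t, v, method = "fmm")
      y <- f(grid)
      y[grid < min(t)] <- v[1L]
      y[grid > max(t)] <- v[length(v)]
      y
    },
    stop("unknown interpolation method: ", method)
  )
  pmax(out, 0)
}

#' Interpolate a time course onto the 2-hour analysis grid
#'
#' Places both channels on the fifty grid times t = 2, 4, ..., 100 h by
#' interpolation (not smoothing): observations that fall exactly on grid
#' points are reproduced. Before the first observation values are
#' back-filled and after the last forward-filled (flat extension), and
#' negative spline interpolants are clipped to 0.
#'
#' @param tc A [timecourse()].
#' @param method `"linear"` (default) or `"cubic_spline"`.
#' @return An object of class `gridded_timecourse` with fields `grid`
#'   (hours), `blood`, `lymph` (percent) and `method`.
#' @export
interpolate_to_grid <- function(tc, method = c("linear", "cubic_spline")) {
  if (!inherits(tc, "timecourse")) stop("tc must be a timecourse")
  method <- match.arg(method)
  blood <- interp_channel(tc$time_h, tc$pct_blood, GRID_H, method)
  lymph <- interp_channel(tc$time_h, tc$pct_lymph, GRID_H, method)
  stopifnot(length(blood) == N_BINS, all(is.finite(blood)),
            all(is.finite(lymph)))
  structure(list(animal_id = tc$animal_id, grid = GRID_H,
                 blood = blood, lymph = lymph, method = method),
            class = "gridded_timecourse")
}

#' @export
as.data.frame.gridded_timecourse <- function(x, ...) {
  data.frame(t_h = x$grid, blood_pct = x$blood, lymph_pct = x$lymph,
             method = x$method)
}

# Lower-triangular lagged-input matrix from a gridded blood vector.
# B[i, j] = blood(t_i - theta_j) with theta_j = 2j; the lag-0 value
# (j == i) is taken as the gridded value at the smallest grid time.
lagged_input_matrix <- function(blood) {
  n <- length(blood)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lags <- i - seq_len(i)              # i - j for j = 1..i
    B[i, seq_len(i)] <- blood[pmax(lags, 1L)]
  }
  B
}

#' Assemble the convolution system L = c B p
#'
#' Builds the lower-triangular input matrix B whose entry (i, j) is the
#' gridded blood percentage at time t_i - theta_j (theta_j = 2j h), the
#' efflux vector L from the gridded lymph channel, and an initially unset
#' proportionality constant c (see [estimate_c()]). Blood at lag zero is
#' taken as the gridded value at the smallest grid time.
#'
#' @param g A `gridded_timecourse` from [interpolate_to_grid()].
#' @return An object of class `convolution_system` with fields `B` (50x50),
#'   `L` (length 50), `c` (NA until estimated), `animal_id`.
#' @export
build_convolution_system <- function(g) {
  if (!inherits(g, "gridded_timecourse")) stop("g must be a gridded_timecourse")
  B <- lagged_input_matrix(g$blood)
  stopifnot(all(B[upper.tri(B)] == 0), all(B >= 0), all(g$lymph >= 0))
  structure(list(animal_id = g$animal_id, B = B, L = g$lymph, c = NA_real_),
            class = "convolution_system")
}

#' @export
print.convolution_system <- function(x, ...) {
  cat("<convolution_system> animal", x$animal_id, "- 50x50 input matrix, c =",
      if (is.na(x$c)) "unset" else signif(x$c, 4), "\n")
  invisible(x)
}
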