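#' Fit a cubic spline to one measured time series
#'
#' Maps a raw series into spline space: either a natural cubic interpolating
#' spline (reproduces every input point exactly) or a smoothing spline with
#' the smoothing parameter chosen by generalized cross-validation. Optionally
#' the fit is done on the log scale; series containing non-positive values
#' get an offset `1e-6 + |min(values)|` added before the log, which is
#' recorded and inverted on evaluation.
#'
#' Evaluation outside the observed time range is refused (no extrapolation).
#'
#' @param times Strictly increasing numeric vector (at least 4 points).
#' @param values Numeric vector of the same length; `NA` pairs are dropped.
#' @param variant `"interpolating"` or `"smoothing"`.
#' @param log_scale Fit on the log scale?
#' @param spar Optional smoothing parameter override for the smoothing
#'   variant (default: generalized cross-validation).
#' @return An object of class `spline_fit`.
#' @export
fit_spline <- function(times, values, variant = c("interpolating", "smoothing"),
                       log_scale = FALSE, spar = NULL) {
  variant <- match.arg(variant)
  keep <- !is.na(times) & !is.na(values)
  times <- times[keep]; values <- values[keep]
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  if (length(times) < 4L) {
    abort(paste("A cubic fit needs at least 4 points;",
                "use the piecewise-linear (no-spline) mode for shorter series."))
  }
  offset <- 0
  w <- values
  if (log_scale) {
    if (min(values) <= 0) offset <- 1e-6 + abs(min(values))
    w <- log(values + offset)
  }
  fun <- if (variant == "interpolating") {
    stats::splinefun(times, w, method = "natural")
  } else {
    sp <- if (is.null(spar)) stats::smooth.spline(times, w) else
      stats::smooth.spline(times, w, spar = spar)
    function(t) stats::predict(sp, t)$y
  }
  structure(list(fun = fun, range = range(times), n_points = length(times),
                 times = times, variant = variant,
                 log_scale = log_scale, offset = offset),
            class = "spline_fit")
}

#' Evaluate a spline fit
#'
#' @param object A `spline_fit`.
#' @param times Evaluation times, all within the fitted range.
#' @param ... Unused.
#' @export
predict.spline_fit <- function(object, times, ...) {
  if (any(times < object$range[1] - 1e-12) || any(times > object$range[2] + 1e-12)) {
    abort(sprintf("Evaluation outside the observed time range [%g, %g] is not supported.",
                  object$range[1], object$range[2]))
  }
  v <- object$fun(times)
  if (object$log_scale) v <- exp(v) - object$offset
  v
}

#' Resample a fitted series to a denser uniform grid
#'
#' Returns values on a uniform grid of `n_points` spanning the original time
#' range (endpoints included). Upsampling only: interpolated series at higher
#' resolution feed the discretized model in place of the raw data.
#'
#' @param fit A `spline_fit`.
#' @param n_points Number of grid points, at least the original count.
#' @return Tibble with columns `time`, `value`.
#' @export
resample_series <- function(fit, n_points) {
  if (n_points < fit$n_points) {
    abort(sprintf("Upsampling only: n_points (%d) must be >= the original count (%d).",
                  n_points, fit$n_points))
  }
  times <- seq(fit$range[1], fit$range[2], length.out = n_points)
  tibble::tibble(time = times, value = predict(fit, times))
}

#' Mean-center every measured time series
#'
#' Normalization used for signalling-array style data: subtracts from each
#' (molecule, replicate, condition) series its own mean, leaving perturbation
#' signals untouched.
#'
#' @param dataset A time-series [pert_dataset].
#' @export
mean_center <- function(dataset) {
  if (dataset$mode != "timeseries") abort("mean_center() expects time-series mode.")
  dataset$blocks <- purrr::map(dataset$blocks, function(b) {
    mu <- colMeans(b$y, na.rm = TRUE)
    b$y <- sweep(b$y, 2, ifelse(is.finite(mu), mu, 0))
    b
  })
  dataset
}

#' Per-series measurement bounds
#'
#' The minimum and maximum measured value of each molecule in each replicate
#' of each condition over the whole series; these bound the clipped response.
#' Recomputed from data only, never from model output.
#'
#' @param dataset A [pert_dataset].
#' @return Tibble with columns condition, replicate, molecule, lower, upper.
#' @export
compute_clip_bounds <- function(dataset) {
  out <- purrr::map_dfr(dataset$blocks, function(b) {
    all_na <- apply(b$y, 2, function(col) all(is.na(col)))
    if (any(all_na)) {
      abort(sprintf("All values missing for series: %s (condition %s, replicate %s).",
                    paste(colnames(b$y)[all_na], collapse = ", "),
                    b$condition, b$replicate))
    }
    tibble::tibble(condition = b$condition, replicate = b$replicate,
                   molecule = colnames(b$y),
                   lower = unname(apply(b$y, 2, min, na.rm = TRUE)),
                   upper = unname(apply(b$y, 2, max, na.rm = TRUE)))
  })
  class(out) <- c("clip_bounds", class(out))
  out
}

#' Spline-resample a whole dataset
#'
#' Applies [fit_spline] + [resample_series] to every measured series,
#' producing a dataset on a denser uniform per-block grid. Perturbation
#' signals are design variables, not measurements, and are carried over by
#' zero-order-hold (step) interpolation.
#'
#' @param dataset A time-series [pert_dataset].
#' @param variant `"none"`, `"interpolating"` or `"smoothing"`.
#' @param n_points Target grid size per block (upsampling only).
#' @param log_scale Fit splines on the log scale?
#' @param center Mean-center each series first?
#' @export
preprocess_dataset <- function(dataset, variant = c("none", "interpolating", "smoothing"),
                               n_points = NULL, log_scale = FALSE, center = FALSE) {
  variant <- match.arg(variant)
  if (center) dataset <- mean_center(dataset)
  if (variant == "none") return(dataset)
  if (dataset$mode != "timeseries") abort("Spline preprocessing expects time-series mode.")
  if (is.null(n_points)) abort("`n_points` is required for spline preprocessing.")
  dataset$blocks <- purrr::map(dataset$blocks, function(b) {
    grid <- seq(min(b$times), max(b$times), length.out = n_points)
    y <- apply(b$y, 2, function(v) {
      fit <- fit_spline(b$times, v, variant = variant, log_scale = log_scale)
      predict(fit, grid)
    })
    x <- if (ncol(b$x)) {
      apply(b$x, 2, function(v) {
        approx(b$times, v, xout = grid, method = "constant", f = 0, rule = 2)$y
      })
    } else matrix(numeric(0), n_points, 0)
    if (!is.matrix(y)) y <- matrix(y, nrow = n_points)
    if (!is.matrix(x)) x <- matrix(x, nrow = n_points)
    colnames(y) <- dataset$molecules; colnames(x) <- dataset$perturbations
    list(condition = b$condition, replicate = b$replicate, times = grid, y = y, x = x)
  })
  dataset
}
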