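#' Summary-statistic specification of a marker distribution
#'
#' A distribution summarized the way screening studies report skewed
#' variables: median with 2.5th and 97.5th percentiles.
#'
#' @param median Median of the distribution (marker units or MoM).
#' @param p_low 2.5th percentile.
#' @param p_high 97.5th percentile.
#' @return An object of class `percentile_spec`.
#' @examples
#' percentile_spec(1.59, 0.61, 3.61)
#' @export
percentile_spec <- function(median, p_low, p_high) {
  check_number(median, "median")
  check_number(p_low, "p_low")
  check_number(p_high, "p_high")
  if (p_low > median) abort("`p_low` must not exceed `median`")
  if (median > p_high) abort("`median` must not exceed `p_high`")
  structure(list(median = median, p_low = p_low, p_high = p_high),
            class = "percentile_spec")
}

#' @export
print.percentile_spec <- function(x, ...) {
  cat(sprintf("%g (%g-%g)\n", x$median, x$p_low, x$p_high))
  invisible(x)
}

#' Calibrate a two-piece log-normal to a median and outer percentiles
#'
#' Fits a split ("two-piece") log-normal whose median and 2.5th/97.5th
#' percentiles reproduce the supplied summary exactly. On the log scale the
#' variable is `mu + sigma(z) * z` with `z` standard normal, where
#' `sigma(z)` is `sigma_lower` for `z < 0` and `sigma_upper` otherwise;
#' each scale comes from its own percentile through the 1.959964
#' (`qnorm(0.975)`) conversion. The split family accommodates the
#' asymmetric intervals typical of MoM distributions; with
#' `pooled = TRUE` a single log-normal is fitted instead, with one sigma
#' from the full percentile span (the median is still reproduced exactly,
#' the outer percentiles only if the printed interval happens to be
#' log-symmetric).
#'
#' @param spec A [percentile_spec()]; all three values must be positive.
#' @param pooled Use a single common sigma instead of the split form.
#' @return An object of class `two_piece` with fields `location` (log
#'   median), `sigma_lower`, `sigma_upper` and `log_scale = TRUE`.
#' @seealso [fit_two_piece_normal()] for the natural-scale analogue,
#'   [rtwo_piece()], [qtwo_piece()].
#' @export
fit_two_piece_lognormal <- function(spec, pooled = FALSE) {
  stopifnot(inherits(spec, "percentile_spec"))
  check_positive(spec$p_low, "p_low")
  check_positive(spec$median, "median")
  check_positive(spec$p_high, "p_high")
  mu <- log(spec$median)
  if (pooled) {
    s <- (log(spec$p_high) - log(spec$p_low)) / (2 * Z_P975)
    sl <- su <- s
  } else {
    sl <- (mu - log(spec$p_low)) / Z_P975
    su <- (log(spec$p_high) - mu) / Z_P975
  }
  structure(list(location = mu, sigma_lower = sl, sigma_upper = su,
                 log_scale = TRUE),
            class = "two_piece")
}

#' Calibrate a two-piece normal on the natural scale
#'
#' Same split construction as [fit_two_piece_lognormal()] but applied to
#' the raw values (no log transform); used for near-symmetric quantities
#' such as maternal age, weight and gestational age.
#'
#' @inheritParams fit_two_piece_lognormal
#' @return A `two_piece` object with `log_scale = FALSE`.
#' @export
fit_two_piece_normal <- function(spec, pooled = FALSE) {
  stopifnot(inherits(spec, "percentile_spec"))
  mu <- spec$median
  if (pooled) {
    s <- (spec$p_high - spec$p_low) / (2 * Z_P975)
    sl <- su <- s
  } else {
    sl <- (mu - spec$p_low) / Z_P975
    su <- (spec$p_high - mu) / Z_P975
  }
  structure(list(location = mu, sigma_lower = sl, sigma_upper = su,
                 log_scale = FALSE),
            class = "two_piece")
}

# core transform: standard-normal z -> two-piece variate
tp_transform <- function(z, fit) {
  s <- ifelse(z < 0, fit$sigma_lower, fit$sigma_upper)
  y <- fit$location + s * z
  if (fit$log_scale) exp(y) else y
}

#' Quantile function of a calibrated two-piece distribution
#'
#' @param p Probabilities.
#' @param fit A `two_piece` object.
#' @return Quantiles; `qtwo_piece(0.5, fit)` is the calibrated median and
#'   `qtwo_piece(c(0.025, 0.975), fit)` the calibrated outer percentiles.
#' @export
qtwo_piece <- function(p, fit) {
  stopifnot(inherits(fit, "two_piece"), all(p >= 0 & p <= 1))
  tp_transform(stats::qnorm(p), fit)
}

#' Draw from a calibrated two-piece distribution
#'
#' @param n Number of draws (ignored when `z` is given).
#' @param fit A `two_piece` object.
#' @param z Optional pre-drawn standard-normal deviates; supplying
#'   correlated normals here is how the Gaussian copula couples markers.
#' @export
rtwo_piece <- function(n, fit, z = NULL) {
  stopifnot(inherits(fit, "two_piece"))
  if (is.null(z)) z <- stats::rnorm(n)
  tp_transform(z, fit)
}
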