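#' Gestational-age median curve
#'
#' Median marker concentration as a function of gestational age, modelled
#' as 10 raised to a quartic polynomial in GA (days):
#' `median = 10^(c0 + c1*GA + c2*GA^2 + c3*GA^3 + c4*GA^4)`.
#'
#' @param coefficients Numeric vector `c(c0, c1, c2, c3, c4)`.
#' @return An object of class `ga_median_model`.
#' @seealso [afp_l2_ga_model()] for the built-in AFP-L2 coefficient set,
#'   [identity_ga_model()] for a constant median of 1.
#' @export
ga_median_model <- function(coefficients) {
  if (!is.numeric(coefficients) || length(coefficients) != 5L ||
      any(!is.finite(coefficients))) {
    abort("`coefficients` must be 5 finite numbers (c0..c4)")
  }
  structure(list(coefficients = as.numeric(coefficients)),
            class = "ga_median_model")
}

#' Built-in AFP-L2 gestational-age median coefficients
#'
#' The only marker for which a published quartic coefficient set is
#' available to this package; other markers default to the identity
#' median unless coefficients are supplied through configuration.
#'
#' @return A [ga_median_model()].
#' @export
afp_l2_ga_model <- function() {
  ga_median_model(c(-261.9, 8.09, -0.09277, 0.0004694, -0.0000008842))
}

#' @rdname ga_median_model
#' @export
identity_ga_model <- function() ga_median_model(c(0, 0, 0, 0, 0))

# supported GA range (days) for the median curves; outside we warn but
# still evaluate
GA_RANGE <- c(77, 97)

#' Evaluate a gestational-age median curve
#'
#' Horner evaluation of the quartic, then `10^`. GA outside the supported
#' 77-97 day window triggers a warning but is still evaluated.
#'
#' @param ga_days Gestational age in days (vectorized).
#' @param model A [ga_median_model()].
#' @return Positive median values.
#' @export
ga_median <- function(ga_days, model = afp_l2_ga_model()) {
  stopifnot(inherits(model, "ga_median_model"))
  if (!is.numeric(ga_days) || any(!is.finite(ga_days))) {
    abort("`ga_days` must be finite")
  }
  if (any(ga_days < GA_RANGE[1] | ga_days > GA_RANGE[2])) {
    warning(sprintf("ga_days outside supported range [%g, %g]",
                    GA_RANGE[1], GA_RANGE[2]), call. = FALSE)
  }
  co <- model$coefficients
  p <- co[1] + ga_days * (co[2] + ga_days * (co[3] + ga_days * (co[4] + ga_days * co[5])))
  out <- 10^p
  if (any(!is.finite(out))) {
    abort("ga_median: non-finite median at ga_days = ",
          paste(ga_days[!is.finite(out)], collapse = ", "))
  }
  out
}

#' Maternal-weight median correction
#'
#' Hyperbolic correction `a - b / weight` with weight in kg.
#'
#' @param a,b Model constants; defaults are the published set
#'   (`a = 0.8852`, `b = 9.465`).
#' @return An object of class `weight_median_model`.
#' @export
weight_median_model <- function(a = 0.8852, b = 9.465) {
  check_number(a, "a"); check_number(b, "b")
  structure(list(a = a, b = b), class = "weight_median_model")
}

#' @rdname ga_median_model
#' @export
identity_weight_model <- function() weight_median_model(a = 1, b = 0)

#' Evaluate the maternal-weight median correction
#'
#' @param weight_kg Maternal weight in kg (vectorized); must exceed `b/a`
#'   so the correction stays positive.
#' @param model A [weight_median_model()].
#' @return Positive correction factors `a - b / weight_kg`.
#' @export
weight_median <- function(weight_kg, model = weight_median_model()) {
  stopifnot(inherits(model, "weight_median_model"))
  check_positive(weight_kg, "weight_kg")
  out <- model$a - model$b / weight_kg
  # <= 1e-12 rather than <= 0 so the pole at weight = b/a is caught even
  # when floating-point round-trip leaves a sliver above zero
  if (any(out <= 1e-12)) {
    abort(sprintf(
      "weight correction non-positive at weight_kg = %s (requires weight > b/a = %g)",
      paste(weight_kg[out <= 1e-12], collapse = ", "),
      model$b / model$a))
  }
  out
}

#' Multiple of the median
#'
#' @param concentration Raw marker concentration(s), positive.
#' @param population_median Population median of the same marker, positive.
#' @return `concentration / population_median`.
#' @export
raw_mom <- function(concentration, population_median) {
  check_positive(concentration, "concentration")
  check_positive(population_median, "population_median")
  concentration / population_median
}

#' Gestational-age- and weight-adjusted MoM
#'
#' Divides a MoM value by the product of the gestational-age median and
#' the maternal-weight correction. This exact form (MoM over the product
#' of the two median terms) is the published convention this package
#' reproduces; see [normalize_cohort()] for the conventional sequential
#' variant.
#'
#' @param mom MoM value(s), positive.
#' @param ga_med Gestational-age median value(s), positive.
#' @param weight_med Weight correction value(s), positive.
#' @return `mom / (ga_med * weight_med)`.
#' @export
adjusted_mom <- function(mom, ga_med, weight_med) {
  check_positive(mom, "mom")
  check_positive(ga_med, "ga_med")
  check_positive(weight_med, "weight_med")
  mom / (ga_med * weight_med)
}

#' Default per-marker median models
#'
#' AFP-L2 uses the built-in published quartic GA curve and weight
#' hyperbola; the other markers (for which no coefficients are published)
#' default to identity medians, i.e. their MoM values pass through
#' unchanged.
#'
#' @return Named list, one `list(ga = , weight = )` entry per panel marker.
#' @export
default_median_models <- function() {
  out <- lapply(MARKER_PANEL, function(m) identity_median_model())
  names(out) <- MARKER_PANEL
  out$afp_l2 <- list(ga = afp_l2_ga_model(), weight = weight_median_model())
  out
}

identity_median_model <- function() {
  list(ga = identity_ga_model(), weight = identity_weight_model())
}

#' Convert a gestational age in completed weeks (+ days) to days
#'
#' I/O convenience only; every model in the package works in days.
#'
#' @param weeks Completed weeks.
#' @param days Additional days (default 0).
#' @export
ga_weeks_to_days <- function(weeks, days = 0) weeks * 7 + days

#' Normalize a cohort's raw marker values to adjusted MoM
#'
#' Converts `<marker>_raw` columns to `<marker>_mom`. In the default
#' `"published"` mode the raw value is first divided by the population
#' median and the resulting MoM is then divided by the product of the
#' GA median and the weight correction. The `"conventional"` mode applies
#' the usual screening pipeline instead (raw over GA median, then weight
#' correction).
#'
#' @param cohort Cohort data.frame with `*_raw`, `ga_days` and
#'   `maternal_weight_kg` columns.
#' @param median_models As [default_median_models()].
#' @param population_medians Named numeric vector of population medians
#'   per marker (default 1 for all, the convention of the synthetic
#'   pseudo-raw mode).
#' @param mode `"published"` (default) or `"conventional"`.
#' @return The cohort with `<marker>_mom` columns replaced/added.
#' @export
normalize_cohort <- function(cohort, median_models = default_median_models(),
                             population_medians = NULL,
                             mode = c("published", "conventional")) {
  mode <- match.arg(mode)
  markers <- MARKER_PANEL[raw_col(MARKER_PANEL) %in% names(cohort)]
  if (!length(markers)) {
    if (length(cohort_markers(cohort))) return(cohort)  # already in MoM
    abort("cohort has neither *_raw nor *_mom marker columns")
  }
  for (m in markers) {
    mm <- median_models[[m]]
    if (is.null(mm)) mm <- identity_median_model()
    pop <- if (is.null(population_medians)) 1 else {
      p <- population_medians[[m]]
      if (is.null(p) || is.na(p)) 1 else p
    }
    gm <- ga_median(cohort$ga_days, mm$ga)
    wm <- weight_median(cohort$maternal_weight_kg, mm$weight)
    cohort[[mom_col(m)]] <- switch(mode,
      published    = adjusted_mom(raw_mom(cohort[[raw_col(m)]], pop), gm, wm),
      conventional = raw_mom(cohort[[raw_col(m)]], pop * gm) / wm
    )
  }
  cohort
}
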