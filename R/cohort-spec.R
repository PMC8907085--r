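#' Specification of one outcome group of a synthetic cohort
#'
#' @param n Number of subjects.
#' @param age,weight,ga_days [percentile_spec()] summaries of maternal age
#'   (years), maternal weight (kg) and gestational age (days).
#' @param markers Named list of [percentile_spec()] objects on the MoM
#'   scale; names must come from [marker_panel()].
#' @param label Outcome class, `"affected"` or `"control"`.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(n, age, weight, ga_days, markers, label) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    abort("`n` must be a non-negative integer")
  }
  label <- match.arg(label, GROUP_LEVELS)
  for (f in list(age, weight, ga_days)) stopifnot(inherits(f, "percentile_spec"))
  if (!length(markers) || is.null(names(markers))) {
    abort("`markers` must be a named list of percentile_spec objects")
  }
  bad <- setdiff(names(markers), MARKER_PANEL)
  if (length(bad)) {
    abort("unknown marker name(s): ", paste(bad, collapse = ", "),
          "; panel is ", paste(MARKER_PANEL, collapse = ", "))
  }
  for (m in markers) stopifnot(inherits(m, "percentile_spec"))
  structure(list(n = as.integer(n), age = age, weight = weight,
                 ga_days = ga_days, markers = markers, label = label),
            class = "group_spec")
}

#' Specification of a two-group synthetic screening cohort
#'
#' @param affected,control [group_spec()] objects; both must cover the
#'   same marker set.
#' @param correlation Inter-marker correlation matrix on the log-MoM scale
#'   (Gaussian-copula parameter). Must be symmetric positive semidefinite
#'   with unit diagonal. Default identity (independent markers).
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(affected, control, correlation = NULL, seed = 1L) {
  stopifnot(inherits(affected, "group_spec"), inherits(control, "group_spec"))
  if (!setequal(names(affected$markers), names(control$markers))) {
    abort("affected and control groups must specify the same markers")
  }
  markers <- names(affected$markers)
  k <- length(markers)
  if (is.null(correlation)) correlation <- diag(k)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(dim(correlation), c(k, k)))) {
    abort("`correlation` must be a ", k, "x", k, " matrix")
  }
  if (!isSymmetric(unname(correlation), tol = 1e-10)) {
    abort("`correlation` must be symmetric")
  }
  if (any(abs(diag(correlation) - 1) > 1e-10)) {
    abort("`correlation` must have unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort("`correlation` must be positive semidefinite (smallest eigenvalue ",
          format(min(ev)), ")")
  }
  dimnames(correlation) <- list(markers, markers)
  structure(list(affected = affected, control = control,
                 correlation = correlation, markers = markers,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  affected: n = %d, control: n = %d\n",
              x$affected$n, x$control$n))
  cat("  markers:", paste(MARKER_LABELS[x$markers], collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Default calibrated cohort specification
#'
#' The package's reference study conditions: a 40 + 40 first-trimester
#' case-control cohort whose maternal age/weight/gestational-age and
#' per-marker MoM distributions are calibrated to the published summary
#' statistics (median and 2.5th-97.5th percentiles) of a trisomy 21
#' screening study of that size. Markers are independent by default
#' (no inter-marker correlations are published for this cohort); pass a
#' different `correlation` to impose one.
#'
#' @param n_affected,n_control Group sizes (default 40 each, the study
#'   design being emulated).
#' @param correlation Optional 4x4 correlation matrix (see [cohort_spec()]).
#' @param seed Seed stored in the spec; default 20211108.
#' @return A [cohort_spec()].
#' @examples
#' spec <- default_cohort_spec()
#' spec$affected$markers$afp_l2$median  # 1.59 MoM
#' @export
default_cohort_spec <- function(n_affected = 40L, n_control = 40L,
                                correlation = NULL, seed = 20211108L) {
  control <- group_spec(
    n = n_control,
    age     = percentile_spec(28.44, 20.35, 33.86),
    weight  = percentile_spec(50.10, 42.90, 63.00),
    ga_days = percentile_spec(89.00, 80.05, 97.00),
    markers = list(
      papp_a    = percentile_spec(0.88, 0.20, 3.74),
      free_bhcg = percentile_spec(1.02, 0.33, 3.98),
      nt        = percentile_spec(0.87, 0.59, 1.15),
      afp_l2    = percentile_spec(1.00, 0.39, 2.12)
    ),
    label = "control"
  )
  affected <- group_spec(
    n = n_affected,
    age     = percentile_spec(29.92, 24.11, 37.79),
    weight  = percentile_spec(53.30, 39.13, 74.73),
    ga_days = percentile_spec(87.00, 69.10, 96.98),
    markers = list(
      papp_a    = percentile_spec(0.37, 0.04, 1.65),
      free_bhcg = percentile_spec(1.76, 0.15, 6.95),
      nt        = percentile_spec(1.17, 0.59, 2.10),
      afp_l2    = percentile_spec(1.59, 0.61, 3.61)
    ),
    label = "affected"
  )
  cohort_spec(affected, control, correlation = correlation, seed = seed)
}

spec_to_list <- function(x) {
  ps <- function(p) list(median = p$median, p_low = p$p_low, p_high = p$p_high)
  gs <- function(g) list(
    n = g$n, label = g$label, age = ps(g$age), weight = ps(g$weight),
    ga_days = ps(g$ga_days), markers = lapply(g$markers, ps)
  )
  list(affected = gs(x$affected), control = gs(x$control),
       correlation = apply(x$correlation, 1, as.list),
       markers = x$markers, seed = x$seed)
}

#' Read or write a cohort specification as YAML
#'
#' The on-disk schema mirrors the [cohort_spec()] structure; an annotated
#' example ships with the package at
#' `system.file("extdata", "cohort_spec_example.yaml", package = "t21screen")`.
#'
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @return `read_cohort_spec()` returns a `cohort_spec`;
#'   `write_cohort_spec()` returns `path` invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  yaml::write_yaml(spec_to_list(spec), path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  ps <- function(p) percentile_spec(p$median, p$p_low, p$p_high)
  gs <- function(g) group_spec(
    n = g$n, label = g$label, age = ps(g$age), weight = ps(g$weight),
    ga_days = ps(g$ga_days), markers = lapply(g$markers, ps)
  )
  corr <- NULL
  if (!is.null(x$correlation)) {
    corr <- do.call(rbind, lapply(x$correlation, unlist))
  }
  cohort_spec(gs(x$affected), gs(x$control), correlation = corr,
              seed = if (is.null(x$seed)) 1L else x$seed)
}
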