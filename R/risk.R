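#' Maternal-age prior risk parameters
#'
#' The age-only prior risk of a trisomy 21 pregnancy is
#' `k0 + exp(alpha + beta * (age - offset))`. The defaults are the
#' published constant set this package reproduces; all four are
#' configurable for sensitivity analysis.
#'
#' @param k0 Additive floor (risk at very young ages).
#' @param alpha Intercept of the exponential term.
#' @param beta Slope per year of maternal age.
#' @param offset Years subtracted from age before the slope applies.
#' @return An object of class `age_risk_params`.
#' @export
age_risk_params <- function(k0 = 0.0000697, alpha = -18.4367,
                            beta = 0.286, offset = 0.5) {
  for (nm in c("k0", "alpha", "beta", "offset")) check_number(get(nm), nm)
  structure(list(k0 = k0, alpha = alpha, beta = beta, offset = offset),
            class = "age_risk_params")
}

AGE_RANGE <- c(15, 50)

#' Maternal-age prior risk of trisomy 21
#'
#' @param age_years Maternal age in years (vectorized). Ages outside
#'   15-50 y trigger a warning but are still evaluated.
#' @param params An [age_risk_params()].
#' @return Prior risk as a probability, clipped into (0, 1) with a
#'   warning if clipping was needed.
#' @examples
#' maternal_age_risk(c(20, 30, 40))
#' @export
maternal_age_risk <- function(age_years, params = age_risk_params()) {
  stopifnot(inherits(params, "age_risk_params"))
  if (!is.numeric(age_years) || any(!is.finite(age_years))) {
    abort("`age_years` must be finite")
  }
  if (any(age_years < AGE_RANGE[1] | age_years > AGE_RANGE[2])) {
    warning(sprintf("age_years outside supported range [%g, %g]",
                    AGE_RANGE[1], AGE_RANGE[2]), call. = FALSE)
  }
  r <- params$k0 + exp(params$alpha + params$beta * (age_years - params$offset))
  if (any(!is.finite(r))) abort("maternal_age_risk: non-finite result")
  eps <- 1e-12
  if (any(r <= 0) || any(r >= 1)) {
    warning("maternal_age_risk clipped into (0, 1)", call. = FALSE)
    r <- pmin(pmax(r, eps), 1 - eps)
  }
  r
}

#' Fit a class-conditional Gaussian density in log-MoM space
#'
#' Mean vector and unbiased sample covariance of one outcome class's
#' log10 MoM values over a marker subset. A near-singular covariance is
#' repaired by adding a ridge of `1e-8 * trace/k` to the diagonal
#' (escalated if still singular), with a warning -- never silently.
#'
#' @param log_mom Numeric matrix (n subjects x k markers) of log10 MoM
#'   values; column names are the marker subset.
#' @param class_label `"affected"` or `"control"`.
#' @return An object of class `class_density` with fields `markers`,
#'   `mean`, `covariance`, `class_label`, `n`.
#' @export
fit_class_density <- function(log_mom, class_label = c("affected", "control")) {
  class_label <- match.arg(class_label)
  log_mom <- as.matrix(log_mom)
  k <- ncol(log_mom)
  n <- nrow(log_mom)
  if (any(!is.finite(log_mom))) abort("`log_mom` contains missing/non-finite values")
  if (n < k + 2L) {
    abort(sprintf("need at least k + 2 = %d observations to fit a %d-marker density, got %d",
                  k + 2L, k, n))
  }
  markers <- colnames(log_mom)
  if (is.null(markers)) markers <- paste0("m", seq_len(k))
  mu <- colMeans(log_mom)
  sigma <- stats::cov(log_mom)
  ridge <- 1e-8 * sum(diag(sigma)) / k
  if (ridge <= 0) ridge <- 1e-8
  tries <- 0L
  while (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12) {
    if (tries == 0L) {
      warning("fit_class_density: covariance near-singular; ridge added",
              call. = FALSE)
    }
    sigma <- sigma + diag(ridge, k)
    ridge <- ridge * 100
    tries <- tries + 1L
    if (tries > 10L) abort("covariance could not be regularized to positive definite")
  }
  structure(list(markers = markers, mean = mu, covariance = sigma,
                 class_label = class_label, n = n),
            class = "class_density")
}

# log multivariate-normal density via the Cholesky factor; x is n x k
log_dmvnorm <- function(x, mean, covariance) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  k <- length(mean)
  r <- chol(covariance)
  centered <- sweep(x, 2, mean)
  z <- backsolve(r, t(centered), transpose = TRUE)
  quad <- colSums(z^2)
  -0.5 * (k * log(2 * pi) + quad) - sum(log(diag(r)))
}

#' Multivariate Gaussian likelihood ratio
#'
#' Ratio of the affected-class to control-class multivariate normal
#' density at a subject's log10 MoM vector. Computed through
#' log-densities and exponentiated last, so no intermediate overflow
#' occurs for |log LR| up to ~700.
#'
#' @param x Numeric vector (one subject) or matrix (n x k) of log10 MoM
#'   values over the model's marker subset.
#' @param affected,control [fit_class_density()] objects of matching
#'   dimension.
#' @return Positive likelihood ratio(s).
#' @export
likelihood_ratio <- function(x, affected, control) {
  stopifnot(inherits(affected, "class_density"), inherits(control, "class_density"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  k <- length(affected$mean)
  if (length(control$mean) != k || ncol(x) != k) {
    abort(sprintf("dimension mismatch: x has %d columns, affected %d, control %d",
                  ncol(x), k, length(control$mean)))
  }
  exp(log_dmvnorm(x, affected$mean, affected$covariance) -
        log_dmvnorm(x, control$mean, control$covariance))
}

#' Combine the likelihood ratio with the age prior into the final risk
#'
#' The published convention expresses the final risk as the reciprocal
#' "1 in N" denominator `N = 1 / (LR * age risk)`; the companion
#' `risk_probability = LR * age risk` (clipped below 1) is the ascending
#' score used for ROC analysis, since both orderings are equivalent.
#'
#' @param lr Positive likelihood ratio(s).
#' @param age_risk Prior risk(s) in (0, 1).
#' @return A list with `ultimate` (the 1-in-N denominator) and
#'   `risk_probability`.
#' @examples
#' ultimate_risk(2, 0.001)  # ultimate 500: risk doubled, denominator halved
#' @export
ultimate_risk <- function(lr, age_risk) {
  if (any(!is.finite(lr)) || any(lr <= 0)) abort("`lr` must be positive")
  if (any(age_risk <= 0) || any(age_risk >= 1)) {
    abort("`age_risk` must lie strictly within (0, 1)")
  }
  p <- lr * age_risk
  list(ultimate = 1 / p, risk_probability = pmin(p, 1 - 1e-12))
}

#' Enumerate all marker-subset models
#'
#' All non-empty subsets of the marker panel, ordered by subset size then
#' panel order; the four-marker panel yields the 15 models (4 singles,
#' 6 pairs, 4 triples, 1 quadruple). A model's id is its '+'-joined
#' marker names.
#'
#' @param panel Character vector of unique marker names.
#' @return Named list of character vectors; names are the model ids.
#' @examples
#' length(enumerate_models())  # 15
#' @export
enumerate_models <- function(panel = marker_panel()) {
  if (!length(panel)) abort("`panel` must contain at least one marker")
  if (anyDuplicated(panel)) abort("`panel` contains duplicate marker names")
  models <- list()
  for (size in seq_along(panel)) {
    idx <- utils::combn(length(panel), size, simplify = FALSE)
    models <- c(models, lapply(idx, function(i) panel[i]))
  }
  names(models) <- vapply(models, paste, "", collapse = "+")
  models
}

model_id <- function(markers) paste(markers, collapse = "+")

#' Score a cohort under marker-subset likelihood-ratio models
#'
#' For each model (marker subset), fits affected and control Gaussian
#' densities on log10 adjusted MoM -- by resubstitution on the full
#' cohort by default, the design of the study population this package
#' emulates, or by stratified k-fold cross-fitting -- and combines each
#' subject's likelihood ratio with the maternal-age prior.
#'
#' @param cohort Cohort data.frame with `group`, `maternal_age_years` and
#'   `<marker>_mom` columns.
#' @param models List of marker subsets as from [enumerate_models()];
#'   default: all subsets of the markers present in the cohort.
#' @param age_params An [age_risk_params()].
#' @param log_base10 Model on log10 MoM (default) or on the natural MoM
#'   scale (`FALSE`), for sensitivity analysis.
#' @param cv_folds `NULL` for resubstitution, or an integer number of
#'   stratified folds.
#' @return A data.frame with one row per (subject, model): `subject_id`,
#'   `model_id`, `lr`, `age_risk`, `ultimate`, `risk_probability`.
#' @export
score_cohort <- function(cohort, models = NULL,
                         age_params = age_risk_params(),
                         log_base10 = TRUE, cv_folds = NULL) {
  present <- cohort_markers(cohort)
  if (is.null(models)) models <- enumerate_models(present)
  needed <- unique(unlist(models))
  missing <- setdiff(needed, present)
  if (length(missing)) {
    abort("cohort is missing MoM column(s) for marker(s): ",
          paste(missing, collapse = ", "))
  }
  affected <- as_affected(cohort$group)
  if (!any(affected) || all(affected)) {
    abort("cohort must contain both affected and control subjects")
  }
  x_all <- as.matrix(cohort[, mom_col(needed), drop = FALSE])
  if (any(x_all <= 0)) abort("MoM values must be strictly positive")
  x_all <- if (log_base10) log10(x_all) else x_all
  colnames(x_all) <- needed
  age_risk <- maternal_age_risk(cohort$maternal_age_years, age_params)

  folds <- if (is.null(cv_folds)) rep(0L, nrow(cohort)) else {
    assign_folds(affected, as.integer(cv_folds))
  }
  out <- lapply(names(models), function(id) {
    mk <- models[[id]]
    x <- x_all[, mk, drop = FALSE]
    lr <- numeric(nrow(x))
    for (f in unique(folds)) {
      test <- folds == f
      train <- if (is.null(cv_folds)) rep(TRUE, nrow(x)) else !test
      da <- fit_class_density(x[train & affected, , drop = FALSE], "affected")
      dc <- fit_class_density(x[train & !affected, , drop = FALSE], "control")
      lr[test] <- likelihood_ratio(x[test, , drop = FALSE], da, dc)
    }
    u <- ultimate_risk(lr, age_risk)
    data.frame(subject_id = cohort$subject_id, model_id = id,
               lr = lr, age_risk = age_risk,
               ultimate = u$ultimate, risk_probability = u$risk_probability,
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, out)
  rownames(scores) <- NULL
  attr(scores, "models") <- models
  scores
}

# stratified fold assignment, deterministic given the cohort order
assign_folds <- function(affected, k) {
  if (k < 2L) abort("`cv_folds` must be at least 2")
  folds <- integer(length(affected))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(affected == cls)
    if (length(idx) < k) abort("too few subjects in one class for ", k, " folds")
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
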