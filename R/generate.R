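# plausibility bounds applied to simulated demographics; draws outside are
# clamped and the clamping reported
TRUNC_BOUNDS <- list(
  maternal_age_years = c(15, 50),
  maternal_weight_kg = c(30, 150),
  ga_days            = c(77, 97)
)

truncate_logged <- function(x, what) {
  b <- TRUNC_BOUNDS[[what]]
  n_out <- sum(x < b[1] | x > b[2])
  if (n_out > 0) {
    message(sprintf("generate_cohort: %d %s value(s) truncated to [%g, %g]",
                    n_out, what, b[1], b[2]))
  }
  pmin(pmax(x, b[1]), b[2])
}

generate_group <- function(g, corr_chol, markers, pooled) {
  n <- g$n
  out <- data.frame(
    group = rep(g$label, n),
    maternal_age_years = truncate_logged(
      rtwo_piece(n, fit_two_piece_normal(g$age, pooled)), "maternal_age_years"),
    maternal_weight_kg = truncate_logged(
      rtwo_piece(n, fit_two_piece_normal(g$weight, pooled)), "maternal_weight_kg"),
    ga_days = truncate_logged(
      rtwo_piece(n, fit_two_piece_normal(g$ga_days, pooled)), "ga_days"),
    stringsAsFactors = FALSE
  )
  # Gaussian copula: correlated standard normals, then each margin mapped
  # through its own calibrated two-piece log-normal
  k <- length(markers)
  z <- matrix(stats::rnorm(n * k), nrow = n, ncol = k) %*% corr_chol
  for (j in seq_along(markers)) {
    fit <- fit_two_piece_lognormal(g$markers[[markers[j]]], pooled)
    out[[mom_col(markers[j])]] <- rtwo_piece(n, fit, z = z[, j])
  }
  out
}

#' Generate a synthetic screening cohort
#'
#' Draws a case-control cohort from a [cohort_spec()]. Marker MoM values
#' come from two-piece log-normals calibrated to each group's percentile
#' summaries, coupled across markers by a Gaussian copula with the spec's
#' correlation matrix; maternal age, weight and gestational age come from
#' natural-scale two-piece distributions, clamped to plausibility bounds
#' (age 15-50 y, weight 30-150 kg, GA 77-97 d) with a message when
#' clamping occurs. Generation is fully determined by `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param pseudo_raw If `TRUE`, also emit `*_raw` columns: the MoM value
#'   multiplied back through the gestational-age and weight median curves
#'   (population median 1), so the normalization stage can be exercised
#'   end-to-end and must recover the `*_mom` columns.
#' @param median_models Per-marker median models used only in
#'   `pseudo_raw` mode; see [default_median_models()].
#' @param pooled Use single (pooled-sigma) log-normal margins instead of
#'   the two-piece family.
#' @return A data.frame with columns `subject_id`, `group`,
#'   `maternal_age_years`, `maternal_weight_kg`, `ga_days` and one
#'   `<marker>_mom` column per marker (plus `<marker>_raw` in pseudo-raw
#'   mode). Affected rows come first.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec())
#' table(cohort$group)
#' @export
generate_cohort <- function(spec, pseudo_raw = FALSE,
                            median_models = default_median_models(),
                            pooled = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  markers <- spec$markers
  corr_chol <- chol_psd(spec$correlation)
  cohort <- with_seed(spec$seed, {
    rbind(
      generate_group(spec$affected, corr_chol, markers, pooled),
      generate_group(spec$control, corr_chol, markers, pooled)
    )
  })
  cohort <- cbind(
    subject_id = sprintf("S%04d", seq_len(nrow(cohort))),
    cohort, stringsAsFactors = FALSE
  )
  rownames(cohort) <- NULL
  if (pseudo_raw) {
    for (m in markers) {
      mm <- median_models[[m]]
      if (is.null(mm)) mm <- identity_median_model()
      cohort[[raw_col(m)]] <- cohort[[mom_col(m)]] *
        ga_median(cohort$ga_days, mm$ga) *
        weight_median(cohort$maternal_weight_kg, mm$weight)
    }
  }
  cohort
}

# upper-triangular factor tolerant of semidefinite correlation matrices
chol_psd <- function(m) {
  r <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(r)) return(r)
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

#' Read or write a cohort CSV
#'
#' Cohorts are exchanged as plain CSV with a leading `#` comment line
#' recording the schema version. Columns are those produced by
#' [generate_cohort()].
#'
#' @param cohort A cohort data.frame.
#' @param path File path.
#' @return `read_cohort()` returns the cohort data.frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# t21screen cohort schema v1", con)
  utils::write.csv(cohort, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) abort("failed to read cohort file '", path, "': ",
                              conditionMessage(e))
  )
  if (nrow(cohort) == 0L) abort("cohort file '", path, "' contains no records")
  required <- c("subject_id", "group")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    abort("cohort file missing required column(s): ",
          paste(missing, collapse = ", "))
  }
  as_affected(cohort$group)  # validates labels
  cohort
}

# markers actually present (as *_mom columns) in a cohort, in panel order
cohort_markers <- function(cohort) {
  MARKER_PANEL[mom_col(MARKER_PANEL) %in% names(cohort)]
}
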