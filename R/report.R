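#' Group comparison table of marker MoM distributions
#'
#' Per-marker medians with 2.5th-97.5th percentiles in each group and the
#' Mann-Whitney Z/p comparing the groups -- the summary layout screening
#' studies print for their marker panel.
#'
#' @param cohort Cohort data.frame with `group` and `<marker>_mom` columns.
#' @return A data.frame with one row per marker.
#' @export
compare_groups <- function(cohort) {
  markers <- cohort_markers(cohort)
  if (!length(markers)) abort("cohort has no *_mom marker columns")
  affected <- as_affected(cohort$group)
  q <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  rows <- lapply(markers, function(m) {
    xa <- cohort[[mom_col(m)]][affected]
    xc <- cohort[[mom_col(m)]][!affected]
    qa <- q(xa); qc <- q(xc)
    mw <- mann_whitney(xa, xc)
    data.frame(marker = m,
               affected_median = qa[2], affected_p2.5 = qa[1], affected_p97.5 = qa[3],
               control_median = qc[2], control_p2.5 = qc[1], control_p97.5 = qc[3],
               z = abs(mw$z), p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# the 7 baseline/extended pairs: every model lacking `added` versus the
# same model with `added` appended
improvement_pairs <- function(models, added = "afp_l2") {
  base_ids <- names(models)[!vapply(models, function(m) added %in% m, TRUE)]
  pairs <- lapply(base_ids, function(b) {
    ext <- model_id(c(models[[b]], added))
    if (!ext %in% names(models)) return(NULL)
    c(base = b, ext = ext)
  })
  do.call(rbind, pairs)
}

#' Full evaluation report over all scored models
#'
#' Drives the complete evaluation surface from a [score_cohort()] table:
#' per-model ROC/AUC/CI with the Youden-optimal operating point (cutoff
#' reported both as a risk probability and in "1 in N" notation),
#' per-model diagnostic metrics at that cutoff, and IDI/NRI improvement
#' statistics for every model pair formed by adding the improvement
#' marker (default AFP-L2) to a model lacking it -- 7 pairs on the full
#' four-marker panel.
#'
#' @param scores Long data.frame from [score_cohort()].
#' @param labels Either the cohort data.frame (with `subject_id` and
#'   `group`) or a vector of group labels named by subject id.
#' @param boot,seed,ci_method Passed to [roc()].
#' @param nri_categories Optional category boundaries for categorical NRI.
#' @param improvement_marker Marker whose addition defines the
#'   improvement comparisons (default `"afp_l2"`).
#' @return An object of class `t21_report`: data.frames `discrimination`
#'   (one row per model), `diagnostics` (one row per model) and
#'   `improvement` (one row per pair), plus the evaluation settings.
#' @export
evaluate_all <- function(scores, labels, boot = 2000L, seed = 1L,
                         ci_method = c("bootstrap", "asymptotic"),
                         nri_categories = NULL,
                         improvement_marker = "afp_l2") {
  ci_method <- match.arg(ci_method)
  lab <- subject_labels(labels)
  models <- attr(scores, "models")
  ids <- unique(scores$model_id)
  if (is.null(models)) {
    models <- lapply(strsplit(ids, "+", fixed = TRUE), identity)
    names(models) <- ids
  }
  missing <- setdiff(names(models), ids)
  if (length(missing)) {
    abort("scores table is missing model(s): ", paste(missing, collapse = ", "))
  }

  score_mat <- list()
  disc <- diag_rows <- list()
  for (id in names(models)) {
    sub <- scores[scores$model_id == id, ]
    grp <- lab[sub$subject_id]
    if (any(is.na(grp))) abort("labels missing for some scored subjects")
    r <- roc(sub$risk_probability, grp, boot = boot, seed = seed,
             ci_method = ci_method)
    y <- youden_optimal(r)
    dt <- diagnostic_table(sub$risk_probability, grp, y$cutoff)
    disc[[id]] <- data.frame(
      model_id = id, youden_j = y$youden_j, sensitivity = y$sensitivity,
      specificity = y$specificity, cutoff = y$cutoff,
      cutoff_one_in_n = round(1 / y$cutoff),
      auc = r$auc, auc_ci_low = r$auc_ci_low, auc_ci_high = r$auc_ci_high,
      p_value = r$p_value, stringsAsFactors = FALSE
    )
    diag_rows[[id]] <- data.frame(
      model_id = id, dr = dt$dr, ppv = dt$ppv, npv = dt$npv,
      fpr = dt$fpr, fnr = dt$fnr, plr = dt$plr, nlr = dt$nlr,
      stringsAsFactors = FALSE
    )
    score_mat[[id]] <- stats::setNames(sub$risk_probability, sub$subject_id)
  }

  pairs <- improvement_pairs(models, improvement_marker)
  imp <- NULL
  if (!is.null(pairs)) {
    imp <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      b <- pairs[i, "base"]; e <- pairs[i, "ext"]
      sb <- score_mat[[b]]; se <- score_mat[[e]][names(sb)]
      grp <- lab[names(sb)]
      ii <- idi(sb, se, grp)
      nn <- nri(sb, se, grp, categories = nri_categories)
      data.frame(base_model = b, extended_model = e,
                 idi_pct = 100 * ii$idi, idi_p = ii$p,
                 nri_pct = 100 * nn$nri, nri_p = nn$p,
                 stringsAsFactors = FALSE)
    }))
    rownames(imp) <- NULL
  }

  structure(list(
    discrimination = do.call(rbind, disc),
    diagnostics = do.call(rbind, diag_rows),
    improvement = imp,
    settings = list(boot = boot, seed = seed, ci_method = ci_method,
                    nri_categories = nri_categories,
                    improvement_marker = improvement_marker)
  ), class = "t21_report")
}

subject_labels <- function(labels) {
  if (is.data.frame(labels)) {
    if (!all(c("subject_id", "group") %in% names(labels))) {
      abort("labels data.frame needs `subject_id` and `group` columns")
    }
    return(stats::setNames(as.character(labels$group), labels$subject_id))
  }
  if (is.null(names(labels))) {
    abort("labels must be a cohort data.frame or a vector named by subject id")
  }
  stats::setNames(as.character(labels), names(labels))
}

#' @export
print.t21_report <- function(x, ...) {
  cat("t21screen evaluation report\n")
  cat(sprintf("  %d models; AUC range %.3f-%.3f\n",
              nrow(x$discrimination),
              min(x$discrimination$auc), max(x$discrimination$auc)))
  best <- x$discrimination[which.max(x$discrimination$auc), ]
  cat(sprintf("  best model: %s (AUC %.3f)\n", best$model_id, best$auc))
  if (!is.null(x$improvement)) {
    cat(sprintf("  %d improvement comparisons (adding %s)\n",
                nrow(x$improvement), x$settings$improvement_marker))
  }
  invisible(x)
}

significance_mark <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.05, "*", ""))
}

#' Write an evaluation report to disk
#'
#' Emits `discrimination.tsv`, `diagnostics.tsv`, `improvement.tsv`
#' (with significance marks at 0.05 and 0.001) and a machine-readable
#' `report.json` echoing the evaluation settings.
#'
#' @param report A [evaluate_all()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "t21_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  disc <- report$discrimination
  disc$signif <- significance_mark(disc$p_value)
  tsv(disc, "discrimination.tsv")
  tsv(report$diagnostics, "diagnostics.tsv")
  if (!is.null(report$improvement)) {
    imp <- report$improvement
    imp$idi_signif <- significance_mark(imp$idi_p)
    imp$nri_signif <- significance_mark(imp$nri_p)
    tsv(imp, "improvement.tsv")
  }
  jsonlite::write_json(
    list(settings = report$settings,
         discrimination = report$discrimination,
         diagnostics = report$diagnostics,
         improvement = report$improvement),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
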