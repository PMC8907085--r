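#' Mann-Whitney U test (normal approximation)
#'
#' Two-sided rank-sum comparison of two groups reporting the Z statistic
#' screening studies print alongside the p-value. Uses midranks, the tie
#' correction to the variance, and a 0.5 continuity correction.
#'
#' @param group_a,group_b Numeric vectors, both non-empty.
#' @return A list with `z`, `p`, and `u` (the U statistic of `group_a`).
#' @export
mann_whitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) abort("both groups must be non-empty")
  n1 <- length(group_a); n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) {
    warning("all values tied across both groups; Z = 0, p = 1", call. = FALSE)
    return(list(z = 0, p = 1, u = u))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)  # continuity correction
  list(z = z, p = min(1, 2 * stats::pnorm(-abs(z))), u = u)
}

#' ROC curve with rank-statistic AUC and bootstrap confidence interval
#'
#' The AUC is the Mann-Whitney concordance probability (ties get half
#' credit), identical to the trapezoidal area under the stored curve.
#' The 95% CI and the p-value for H0: AUC = 0.5 come from a seeded
#' stratified bootstrap by default; `ci_method = "asymptotic"` uses the
#' Hanley-McNeil variance of the rank statistic instead.
#'
#' @param scores Numeric risk scores, ascending with disease risk.
#' @param labels Group labels (`"affected"`/`"control"`) or a logical
#'   is-affected vector; both classes must be present.
#' @param boot Number of bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap.
#' @param ci_method `"bootstrap"` (default) or `"asymptotic"`.
#' @return An object of class `t21_roc`: `thresholds` (descending,
#'   from `Inf` to `-Inf`), `sensitivity`, `specificity`, `auc`,
#'   `auc_ci_low`, `auc_ci_high`, `p_value`, `n_affected`, `n_control`.
#' @export
roc <- function(scores, labels, boot = 2000L, seed = 1L,
                ci_method = c("bootstrap", "asymptotic")) {
  ci_method <- match.arg(ci_method)
  affected <- as_affected(labels)
  if (length(scores) != length(affected)) abort("scores and labels differ in length")
  if (any(!is.finite(scores))) abort("`scores` must be finite")
  if (!any(affected) || all(affected)) {
    abort("labels must contain both affected and control subjects")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  case <- scores[affected]; ctrl <- scores[!affected]
  sens <- vapply(thr, function(t) mean(case >= t), 0)
  spec <- vapply(thr, function(t) mean(ctrl < t), 0)
  auc <- auc_rank(case, ctrl)

  n1 <- length(case); n0 <- length(ctrl)
  if (ci_method == "bootstrap") {
    bauc <- with_seed(seed, {
      vapply(seq_len(boot), function(i) {
        auc_rank(case[sample.int(n1, replace = TRUE)],
                 ctrl[sample.int(n0, replace = TRUE)])
      }, 0)
    })
    ci <- unname(stats::quantile(bauc, c(0.025, 0.975)))
    p <- min(1, 2 * min(mean(bauc <= 0.5), mean(bauc >= 0.5)))
  } else {
    se <- hanley_mcneil_se(auc, n1, n0)
    ci <- pmin(pmax(auc + c(-1, 1) * Z_P975 * se, 0), 1)
    p <- if (se == 0) as.numeric(auc == 0.5) else
      min(1, 2 * stats::pnorm(-abs(auc - 0.5) / se))
  }
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[2],
                 p_value = p, n_affected = n1, n_control = n0,
                 ci_method = ci_method),
            class = "t21_roc")
}

# concordance-probability AUC via midranks (half credit for ties)
auc_rank <- function(case, ctrl) {
  n1 <- length(case); n0 <- length(ctrl)
  r <- rank(c(case, ctrl))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

hanley_mcneil_se <- function(auc, n1, n0) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
    (n1 * n0)
  sqrt(max(v, 0))
}

#' @export
print.t21_roc <- function(x, ...) {
  cat(sprintf("ROC: %d affected vs %d control\n", x$n_affected, x$n_control))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f), p = %.4g [%s]\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, x$p_value, x$ci_method))
  invisible(x)
}

#' Youden-optimal operating point
#'
#' The threshold maximizing J = sensitivity + specificity - 1; exact ties
#' are broken toward the higher-specificity (higher) threshold.
#'
#' @param roc A [roc()] result.
#' @return A list with `cutoff`, `youden_j`, `sensitivity`, `specificity`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "t21_roc"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  # thresholds are stored descending, so the first tie has highest
  # specificity; prefer a finite cutoff among ties
  finite <- best[is.finite(roc$thresholds[best])]
  pick <- if (length(finite)) finite[1] else best[1]
  list(cutoff = roc$thresholds[pick], youden_j = j[pick],
       sensitivity = roc$sensitivity[pick], specificity = roc$specificity[pick])
}

#' Diagnostic 2x2-table metrics at a fixed cutoff
#'
#' Subjects with `score >= cutoff` are screen-positive (ties positive).
#' Returns the seven headline screening metrics. When the false-positive
#' rate is 0 the positive likelihood ratio is undefined and reported as
#' `NA` with a warning (screening tables print "-").
#'
#' @param scores Numeric scores.
#' @param labels Group labels as in [roc()].
#' @param cutoff Finite threshold.
#' @return A list with `dr`, `ppv`, `npv`, `fpr`, `fnr`, `plr`, `nlr`
#'   and the underlying counts `tp`, `fn`, `fp`, `tn`.
#' @export
diagnostic_table <- function(scores, labels, cutoff) {
  check_number(cutoff, "cutoff")
  affected <- as_affected(labels)
  pos <- scores >= cutoff
  tp <- sum(pos & affected);  fn <- sum(!pos & affected)
  fp <- sum(pos & !affected); tn <- sum(!pos & !affected)
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  fpr <- 1 - spec
  fnr <- 1 - sens
  ppv <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no screen-positive subjects; PPV undefined", call. = FALSE)
    NA_real_
  }
  npv <- if (tn + fn > 0) tn / (tn + fn) else {
    warning("no screen-negative subjects; NPV undefined", call. = FALSE)
    NA_real_
  }
  plr <- if (fpr > 0) sens / fpr else {
    warning("FPR is 0; positive likelihood ratio undefined", call. = FALSE)
    NA_real_
  }
  nlr <- if (spec > 0) fnr / spec else {
    warning("specificity is 0; negative likelihood ratio undefined", call. = FALSE)
    NA_real_
  }
  list(dr = sens, ppv = ppv, npv = npv, fpr = fpr, fnr = fnr,
       plr = plr, nlr = nlr, tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Integrated discrimination improvement
#'
#' IDI of an extended over a baseline risk model: the change, between
#' models, in mean predicted risk separation of affected from control
#' subjects. The p-value uses the standard paired-difference normal
#' approximation. Scores must be probabilities; a model pair with values
#' outside (0, 1) is min-max rescaled jointly, with a warning.
#'
#' @param base_scores,ext_scores Predicted risks under the baseline and
#'   extended models, same subjects in the same order.
#' @param labels Group labels as in [roc()].
#' @return A list with `idi` (on the probability scale; multiply by 100
#'   for percent) and `p`.
#' @export
idi <- function(base_scores, ext_scores, labels) {
  s <- check_score_pair(base_scores, ext_scores, labels)
  affected <- s$affected
  d <- s$ext - s$base
  idi <- mean(d[affected]) - mean(d[!affected])
  n1 <- sum(affected); n0 <- sum(!affected)
  se <- sqrt(stats::var(d[affected]) / n1 + stats::var(d[!affected]) / n0)
  p <- if (!is.finite(se) || se == 0) {
    if (idi == 0) 1 else 0
  } else min(1, 2 * stats::pnorm(-abs(idi) / se))
  list(idi = idi, p = p)
}

#' Net reclassification improvement
#'
#' Continuous (category-free) NRI by default: net fraction of affected
#' subjects whose risk moves up plus net fraction of controls whose risk
#' moves down when switching from the baseline to the extended model.
#' With `categories` (sorted interior thresholds) the categorical NRI on
#' risk-class movements is computed instead. The p-value is the standard
#' asymptotic normal test.
#'
#' @inheritParams idi
#' @param categories Optional ascending vector of category boundaries on
#'   the risk scale.
#' @return A list with `nri` (maximum 2; multiply by 100 for percent)
#'   and `p`.
#' @export
nri <- function(base_scores, ext_scores, labels, categories = NULL) {
  s <- check_score_pair(base_scores, ext_scores, labels)
  affected <- s$affected
  if (is.null(categories)) {
    up <- s$ext > s$base
    down <- s$ext < s$base
  } else {
    if (is.unsorted(categories)) abort("`categories` must be ascending")
    cb <- findInterval(s$base, categories)
    ce <- findInterval(s$ext, categories)
    up <- ce > cb
    down <- ce < cb
  }
  n1 <- sum(affected); n0 <- sum(!affected)
  pu1 <- mean(up[affected]);  pd1 <- mean(down[affected])
  pu0 <- mean(up[!affected]); pd0 <- mean(down[!affected])
  nri <- (pu1 - pd1) - (pu0 - pd0)
  v <- (pu1 + pd1 - (pu1 - pd1)^2) / n1 + (pu0 + pd0 - (pu0 - pd0)^2) / n0
  p <- if (v <= 0) {
    if (nri == 0) 1 else 0
  } else min(1, 2 * stats::pnorm(-abs(nri) / sqrt(v)))
  list(nri = nri, p = p)
}

check_score_pair <- function(base, ext, labels) {
  affected <- as_affected(labels)
  if (length(base) != length(ext) || length(base) != length(affected)) {
    abort("base scores, extended scores and labels must have equal length")
  }
  if (!any(affected) || all(affected)) {
    abort("labels must contain both affected and control subjects")
  }
  rng <- range(base, ext)
  if (rng[1] < 0 || rng[2] > 1) {
    warning("scores outside (0, 1); model pair min-max rescaled jointly",
            call. = FALSE)
    span <- max(rng[2] - rng[1], .Machine$double.eps)
    base <- (base - rng[1]) / span
    ext <- (ext - rng[1]) / span
  }
  list(base = base, ext = ext, affected = affected)
}
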