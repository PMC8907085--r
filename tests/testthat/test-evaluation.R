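test_that("Mann-Whitney Z/p agree with the exact permutation law and wilcox.test", {
  # identical pooled values: no evidence, p = 1
  expect_warning(res <- mann_whitney(rep(2, 4), rep(2, 3)), "tied")
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)

  # complete separation of 3 vs 3: U = 0 for the low group
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  exact <- mw_exact_permutation_p(c(1, 2, 3), c(4, 5, 6))
  expect_equal(exact, 0.1)  # 2 of the C(6,3) = 20 labelings are as extreme
  # normal approximation with continuity correction is close to exact
  expect_lt(abs(res$p - exact), 0.03)
  # and identical to the reference implementation of the same approximation
  ref <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = FALSE, correct = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)

  # with ties, against the tie-corrected reference
  a <- c(1, 2, 2, 3, 7); b <- c(2, 3, 3, 5, 8, 8)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mann_whitney(a, b)$p, ref$p.value, tolerance = 1e-10)
})

test_that("AFP-L2 group separation is detected in nearly all replicate cohorts", {
  # two n = 40 groups from the calibrated AFP-L2 distributions: the
  # published-strength separation (p < 0.001) is the typical outcome
  # (measured power under this calibration is ~0.88), and detection at
  # 0.05 is essentially certain
  fit_case <- fit_two_piece_lognormal(percentile_spec(1.59, 0.61, 3.61))
  fit_ctrl <- fit_two_piece_lognormal(percentile_spec(1.00, 0.39, 2.12))
  set.seed(777)
  p <- vapply(1:200, function(i) {
    mann_whitney(rtwo_piece(40, fit_case), rtwo_piece(40, fit_ctrl))$p
  }, 0)
  expect_gte(mean(p < 0.001), 0.8)
  expect_gte(mean(p < 0.05), 0.99)
})

test_that("rank-statistic AUC equals the exhaustive pairwise oracle", {
  expect_equal(roc(c(3, 4, 5, 1, 2), c(rep("affected", 3), rep("control", 2)),
                   ci_method = "asymptotic")$auc, 1.0)
  set.seed(11)
  for (i in 1:20) {
    n1 <- sample(2:15, 1); n0 <- sample(2:15, 1)
    scores <- round(c(rnorm(n1, 0.5), rnorm(n0)), 1)  # rounding forces ties
    labels <- rep(c("affected", "control"), c(n1, n0))
    r <- roc(scores, labels, ci_method = "asymptotic")
    expect_equal(r$auc, auc_pairwise(scores[1:n1], scores[-(1:n1)]),
                 tolerance = 1e-12)
    # stored curve integrates to the same AUC (trapezoid over FPR)
    fpr <- 1 - r$specificity
    trap <- sum(diff(fpr) * (head(r$sensitivity, -1) + tail(r$sensitivity, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
    # curve monotonicity in the threshold
    expect_true(all(diff(r$sensitivity) >= 0))
    expect_true(all(diff(r$specificity) <= 0))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  scores <- rnorm(40); labels <- rep(c("affected", "control"), 20)
  a1 <- roc(scores, labels, ci_method = "asymptotic")$auc
  expect_equal(roc(exp(scores), labels, ci_method = "asymptotic")$auc, a1)
  expect_equal(roc(qlogis(plogis(scores)), labels, ci_method = "asymptotic")$auc,
               a1, tolerance = 1e-12)
})

test_that("AUC agrees with pROC on a nontrivial input", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- round(c(rnorm(30, 0.8), rnorm(35)), 1)
  labels <- rep(c("affected", "control"), c(30, 35))
  expect_equal(roc(scores, labels, ci_method = "asymptotic")$auc,
               as.numeric(pROC::auc(pROC::roc(
                 response = labels, predictor = scores,
                 levels = c("control", "affected"), direction = "<",
                 quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("bootstrap CI is seed-deterministic and brackets the point AUC", {
  set.seed(14)
  scores <- c(rnorm(25, 1), rnorm(25))
  labels <- rep(c("affected", "control"), c(25, 25))
  r1 <- roc(scores, labels, boot = 500, seed = 9)
  r2 <- roc(scores, labels, boot = 500, seed = 9)
  expect_identical(r1[c("auc_ci_low", "auc_ci_high", "p_value")],
                   r2[c("auc_ci_low", "auc_ci_high", "p_value")])
  expect_lte(r1$auc_ci_low, r1$auc)
  expect_gte(r1$auc_ci_high, r1$auc)
  expect_error(roc(scores, rep("affected", 50)), "both")
})

test_that("Youden point maximizes J and tracks the density crossing", {
  # perfect separation: J = 1 at a cutoff between the classes
  r <- roc(c(10, 11, 1, 2), rep(c("affected", "control"), each = 2),
           ci_method = "asymptotic")
  y <- youden_optimal(r)
  expect_equal(y$youden_j, 1)
  expect_true(y$cutoff > 2 && y$cutoff <= 10)

  # null scores: J stays near zero
  set.seed(15)
  rn <- roc(rnorm(400), rep(c("affected", "control"), 200),
            ci_method = "asymptotic")
  expect_lt(youden_optimal(rn)$youden_j, 0.2)

  # equal-variance Gaussians N(2,1) vs N(0,1): crossing at 1
  set.seed(16)
  n <- 5000
  rg <- roc(c(rnorm(n, 2), rnorm(n)), rep(c("affected", "control"), each = n),
            ci_method = "asymptotic")
  expect_equal(youden_optimal(rg)$cutoff, 1, tolerance = 0.15)
})

test_that("diagnostic metrics reproduce contingency arithmetic and identities", {
  # TP = 8, FN = 2, FP = 3, TN = 7 at cutoff 0
  scores <- c(rep(1, 8), rep(-1, 2), rep(1, 3), rep(-1, 7))
  labels <- rep(c("affected", "control"), c(10, 10))
  d <- diagnostic_table(scores, labels, 0)
  expect_equal(d$dr, 0.8)
  expect_equal(d$fpr, 0.3)
  expect_equal(d$plr, 8 / 3)
  expect_equal(d$ppv, 8 / 11)
  expect_equal(d$npv, 7 / 9)
  expect_equal(d$nlr, 0.2 / 0.7)

  # perfect separation: +LR undefined at FPR 0 (reported NA, warned)
  expect_warning(
    dp <- diagnostic_table(c(1, 1, -1, -1), rep(c("affected", "control"), each = 2), 0),
    "undefined")
  expect_equal(dp$dr, 1); expect_equal(dp$fpr, 0)
  expect_true(is.na(dp$plr)); expect_equal(dp$nlr, 0)

  # identities on random confusion tables
  set.seed(17)
  for (i in 1:25) {
    n1 <- sample(3:30, 1); n0 <- sample(3:30, 1)
    sc <- rnorm(n1 + n0)
    lb <- rep(c("affected", "control"), c(n1, n0))
    cut <- sc[sample(n1 + n0, 1)]
    dd <- suppressWarnings(diagnostic_table(sc, lb, cut))
    expect_equal(dd$fpr + (1 - dd$fnr) - dd$dr, dd$fpr, tolerance = 1e-12)
    expect_equal(dd$fnr, 1 - dd$dr, tolerance = 1e-12)
    if (!is.na(dd$plr)) expect_equal(dd$plr * dd$fpr, dd$dr, tolerance = 1e-12)
    if (dd$fpr < 1) expect_equal(dd$nlr * (1 - dd$fpr), dd$fnr, tolerance = 1e-12)
  }
})

test_that("IDI matches hand arithmetic on a worked six-subject set", {
  labels <- c("affected", "affected", "affected", "control", "control", "control")
  base <- c(0.60, 0.50, 0.40, 0.45, 0.30, 0.20)
  ext  <- c(0.80, 0.55, 0.50, 0.40, 0.35, 0.10)
  # oracle: difference of mean case-control separations
  sep_ext <- mean(ext[1:3]) - mean(ext[4:6])
  sep_base <- mean(base[1:3]) - mean(base[4:6])
  res <- idi(base, ext, labels)
  expect_equal(res$idi, sep_ext - sep_base)
  expect_equal(res$idi, (0.6166666666666667 - 0.2833333333333333) -
                 (0.5 - 0.3166666666666667), tolerance = 1e-12)

  # degenerate and maximal cases
  same <- idi(base, base, labels)
  expect_equal(same$idi, 0); expect_equal(same$p, 1)
  expect_equal(idi(rep(0.5, 6), c(1, 1, 1, 0, 0, 0) * 0.999998 + 1e-6,
                   labels)$idi, 1, tolerance = 1e-5)

  # antisymmetry under swapping the two models
  expect_equal(idi(ext, base, labels)$idi, -res$idi)
})

test_that("NRI matches exhaustive up/down counting on the worked set", {
  labels <- c("affected", "affected", "affected", "control", "control", "control")
  base <- c(0.60, 0.50, 0.40, 0.45, 0.30, 0.20)
  ext  <- c(0.80, 0.55, 0.50, 0.40, 0.35, 0.10)
  # cases: up, up, up; controls: down, up, down
  oracle <- (3 / 3 - 0 / 3) - (1 / 3 - 2 / 3)
  res <- nri(base, ext, labels)
  expect_equal(res$nri, oracle)
  expect_equal(res$nri, 4 / 3, tolerance = 1e-12)

  expect_equal(nri(base, base, labels)$nri, 0)
  # every case up, every control down: the maximum of 2
  expect_equal(nri(base, base + c(1, 1, 1, -1, -1, -1) * 0.05, labels)$nri, 2)
  # antisymmetry
  expect_equal(nri(ext, base, labels)$nri, -res$nri)

  # categorical variant with one boundary at 0.45
  resc <- nri(base, ext, labels, categories = 0.45)
  # category moves: case2 0.50->0.55 stays high, case3 0.40->0.50 up,
  # control1 0.45->0.40 down, others unchanged
  expect_equal(resc$nri, (1 / 3 - 0) - (0 - 1 / 3))
})

test_that("the full report has the published table shapes and sane nulls", {
  # null cohort: both groups share marker distributions
  spec <- default_cohort_spec(40, 40, seed = 300)
  spec$affected$markers <- spec$control$markers
  spec$affected$age <- spec$control$age
  ch <- suppressMessages(generate_cohort(spec))
  sc <- score_cohort(ch)
  rep0 <- evaluate_all(sc, ch, boot = 200, seed = 5)
  expect_s3_class(rep0, "t21_report")
  expect_equal(nrow(rep0$discrimination), 15L)
  expect_equal(nrow(rep0$diagnostics), 15L)
  expect_equal(nrow(rep0$improvement), 7L)
  expect_lt(max(abs(rep0$discrimination$auc - 0.5)), 0.2)
  expect_lt(max(abs(rep0$improvement$idi_pct)), 10)

  # calibrated cohort: in-sample AUC of nested models never drops by more
  # than bootstrap noise when a marker is added
  ch1 <- suppressMessages(generate_cohort(default_cohort_spec(seed = 301)))
  # +LR warnings expected: well-separated models reach FPR 0 in-sample
  rep1 <- suppressWarnings(
    evaluate_all(score_cohort(ch1), ch1, boot = 200, seed = 5))
  auc <- setNames(rep1$discrimination$auc, rep1$discrimination$model_id)
  for (i in seq_len(nrow(rep1$improvement))) {
    expect_gte(auc[[rep1$improvement$extended_model[i]]],
               auc[[rep1$improvement$base_model[i]]] - 0.05)
  }
  expect_error(evaluate_all(sc[sc$model_id != "nt", ], ch), "missing model")
})
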