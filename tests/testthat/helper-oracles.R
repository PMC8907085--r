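# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: brute-force enumeration and direct arithmetic.

# AUC as the exhaustive fraction of concordant case-control pairs, ties
# counting one half
auc_pairwise <- function(case_scores, control_scores) {
  total <- 0
  for (x in case_scores) {
    for (y in control_scores) {
      total <- total + (x > y) + 0.5 * (x == y)
    }
  }
  total / (length(case_scores) * length(control_scores))
}

# exact two-sided permutation p-value for the Mann-Whitney U statistic:
# enumerate every assignment of the pooled values into groups of the
# observed sizes
mw_exact_permutation_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(b) / 2
  combos <- utils::combn(length(pooled), n1, simplify = FALSE)
  us <- vapply(combos, u_of, 0)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# a minimal scored two-class cohort data.frame for evaluation tests
toy_cohort <- function(case_mom, control_mom, marker = "afp_l2",
                       age = 28) {
  n1 <- length(case_mom); n0 <- length(control_mom)
  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n1 + n0)),
    group = rep(c("affected", "control"), c(n1, n0)),
    maternal_age_years = age,
    maternal_weight_kg = 50,
    ga_days = 89,
    stringsAsFactors = FALSE
  )
  df[[paste0(marker, "_mom")]] <- c(case_mom, control_mom)
  df
}

# band of +/- 3 Monte-Carlo standard errors around a target quantile,
# expressed on the value scale through the fitted quantile function
mc_quantile_band <- function(fit, p, n) {
  se <- sqrt(p * (1 - p) / n)
  qtwo_piece(c(max(p - 3 * se, 0), min(p + 3 * se, 1)), fit)
}
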