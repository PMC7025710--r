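# Step-1 between-group statistics: pooled t, Pearson chi-square (no
# continuity correction), two-sided Fisher exact (point-probability rule),
# and a Lilliefors-corrected Kolmogorov-Smirnov normality screen.

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's t with the pooled variance estimate and
#' `df = n1 + n2 - 2`; two-sided p value. This is the flavor that
#' reproduces published group comparisons computed from printed
#' mean/SD/n summaries (not Welch).
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @return List with `t`, `df`, `p`.
#' @seealso [pooled_t_test_raw()] for the raw-sample form.
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("pooled_t_test: each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) {
    stop("pooled_t_test: SDs must be nonnegative and not both zero")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' @rdname pooled_t_test
#' @param x,y Raw samples for the two groups.
#' @export
pooled_t_test_raw <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  pooled_t_test(mean(x), stats::sd(x), length(x),
                mean(y), stats::sd(y), length(y))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No Yates continuity correction; p from the chi-square distribution with
#' 1 df. All row and column margins must be positive.
#'
#' @param table 2x2 matrix of counts.
#' @return List with `chi2`, `df` (= 1), `p`.
#' @export
pearson_chi2 <- function(table) {
  tab <- as.matrix(table)
  if (any(dim(tab) != 2) || any(tab < 0)) stop("pearson_chi2: need a nonnegative 2x2 table")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("pearson_chi2: zero margin")
  expected <- outer(rs, cs) / sum(tab)
  x2 <- sum((tab - expected)^2 / expected)
  list(chi2 = x2, df = 1, p = stats::pchisq(x2, 1, lower.tail = FALSE))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Point-probability rule: the p value sums the hypergeometric
#' probabilities of every table (with the observed margins) whose
#' probability does not exceed that of the observed table. Degenerate
#' tables (a zero margin) return p = 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p value.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (any(dim(tab) != 2) || any(tab < 0) || any(tab != round(tab))) {
    stop("fisher_exact: need a nonnegative integer 2x2 table")
  }
  m <- sum(tab[1, ])           # size of row 1
  n <- sum(tab[2, ])           # size of row 2
  k <- sum(tab[, 1])           # column-1 total
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Dallal-Wilkinson / Stephens approximation to the null distribution of the
# KS statistic when the normal's mean and SD are estimated from the sample
# (the Lilliefors situation).
.lilliefors_p <- function(D, n) {
  if (n <= 100) {
    Kd <- D
    nd <- n
  } else {
    Kd <- D * (n / 100)^0.49
    nd <- 100
  }
  pvalue <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
                  2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
                  0.974598 / sqrt(nd) + 1.67997 / nd)
  if (pvalue > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    pvalue <- if (KK <= 0.302) 1
    else if (KK <= 0.5) 2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
      138.55152 * KK^3 + 81.218052 * KK^4
    else if (KK <= 0.9) -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
      94.029866 * KK^3 - 32.355711 * KK^4
    else if (KK <= 1.31) 6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
      12.234627 * KK^3 + 2.423045 * KK^4
    else 0
  }
  min(max(pvalue, 0), 1)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS statistic against a normal with sample-estimated mean and
#' SD. Because the parameters are estimated, the default p value uses the
#' Lilliefors-corrected approximation; `lilliefors = FALSE` gives the
#' (anti-conservative) uncorrected asymptotic p. A variable is flagged
#' normal when `p >= 0.05`.
#'
#' @param sample Numeric vector, n >= 5, non-constant.
#' @param variable Optional variable name carried into the result.
#' @param lilliefors Apply the estimated-parameter correction (default).
#' @return List with `variable`, `ks_statistic`, `p_value`, `normal`.
#' @export
ks_normality <- function(sample, variable = NA_character_, lilliefors = TRUE) {
  x <- sort(sample[!is.na(sample)])
  n <- length(x)
  if (n < 5) stop("ks_normality: need at least 5 observations")
  s <- stats::sd(x)
  if (s == 0) stop("ks_normality: constant sample")
  z <- stats::pnorm((x - mean(x)) / s)
  i <- seq_len(n)
  D <- max(i / n - z, z - (i - 1) / n)
  p <- if (lilliefors) {
    .lilliefors_p(D, n)
  } else {
    suppressWarnings(stats::ks.test(sample, "pnorm", mean(x), s)$p.value)
  }
  list(variable = variable, ks_statistic = D, p_value = p, normal = p >= 0.05)
}

.compare_continuous <- c("age_onset", "bmi", "total_chol", "tg", "hdl",
                         "hba1c", "gpt", "creatinine")

#' Between-group comparison table
#'
#' One row per clinical variable family, in the conventional report order:
#' gender, age at onset, BMI, total cholesterol, TG, HDL-C, HbA1c, GPT,
#' creatinine, smoking, statins, fibrates. Continuous variables use the
#' pooled t test; gender and smoking the chi-square test; statins and
#' fibrates (rare exposures) the Fisher exact test.
#'
#' @param cohort A `gada_cohort` containing both groups.
#' @param alpha Significance level recorded in the `significant` column.
#' @return Data frame of class `comparison_table` with columns `variable`,
#'   `test`, `statistic`, `df`, `p_value`, `significant`, and per-group
#'   summaries (`mean/sd` or `count/percent`).
#' @export
compare_table <- function(cohort, alpha = 0.05) {
  g1 <- cohort[cohort$group == "GADA_POS", , drop = FALSE]
  g2 <- cohort[cohort$group == "T2DM", , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2) {
    stop("compare_table: both groups must be present with n >= 2")
  }
  rows <- list()
  add <- function(variable, test, statistic, df, p,
                  s1_mean = NA, s1_sd = NA, s2_mean = NA, s2_sd = NA,
                  c1 = NA, c2 = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = test, statistic = statistic,
      df = df, p_value = p, significant = p < alpha,
      gada_mean = s1_mean, gada_sd = s1_sd,
      t2dm_mean = s2_mean, t2dm_sd = s2_sd,
      gada_count = c1, gada_pct = if (is.na(c1)) NA else 100 * c1 / nrow(g1),
      t2dm_count = c2, t2dm_pct = if (is.na(c2)) NA else 100 * c2 / nrow(g2),
      stringsAsFactors = FALSE)
  }
  add_binary <- function(variable, x1, x2, test) {
    tab <- rbind(c(sum(x1), sum(!x1)), c(sum(x2), sum(!x2)))
    if (test == "CHI2") {
      r <- pearson_chi2(t(tab))  # orientation is immaterial for the statistic
      add(variable, "CHI2", r$chi2, r$df, r$p, c1 = sum(x1), c2 = sum(x2))
    } else {
      p <- fisher_exact(tab)
      add(variable, "FISHER_EXACT", NA_real_, NA_real_, p,
          c1 = sum(x1), c2 = sum(x2))
    }
  }
  add_binary("gender_male", g1$gender == "M", g2$gender == "M", "CHI2")
  for (v in .compare_continuous) {
    r <- pooled_t_test_raw(g1[[v]], g2[[v]])
    add(v, "STUDENT_T", r$t, r$df, r$p,
        mean(g1[[v]]), stats::sd(g1[[v]]), mean(g2[[v]]), stats::sd(g2[[v]]))
  }
  add_binary("smoking", g1$smoking, g2$smoking, "CHI2")
  add_binary("statin", g1$statin, g2$statin, "FISHER")
  add_binary("fibrate", g1$fibrate, g2$fibrate, "FISHER")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}
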