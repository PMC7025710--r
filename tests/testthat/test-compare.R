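# between-group statistics

test_that("pooled t reproduces the published total-cholesterol p value", {
  r <- pooled_t_test(184.0, 46.9, 152, 194.4, 41.9, 358)
  expect_equal(r$df, 508)
  expect_equal(round(r$p, 3), 0.014)
})

test_that("pooled t: null case, textbook case, and raw/summary agreement", {
  r0 <- pooled_t_test(5, 2, 30, 5, 2, 40)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  r <- pooled_t_test(0, 1, 10, 1, 1, 10)
  expect_equal(r$t, -2.236, tolerance = 1e-3)
  expect_equal(r$df, 18)
  expect_equal(round(r$p, 3), 0.038)
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(17, 1, 2)
    y <- rnorm(23, 0.3, 1.5)
    mine <- pooled_t_test_raw(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pooled_t_test(1, 0, 5, 1, 0, 5), "not both zero")
  expect_error(pooled_t_test(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("Pearson chi-square (no continuity correction) matches print and oracle", {
  gender <- matrix(c(74, 202, 78, 156), 2)   # GADA+/T2DM x men/women
  expect_equal(round(pearson_chi2(gender)$p, 3), 0.109)
  smoking <- matrix(c(33, 64, 119, 294), 2)
  expect_equal(round(pearson_chi2(smoking)$p, 3), 0.313)
  prop <- matrix(c(10, 20, 10, 20), 2)
  expect_equal(pearson_chi2(prop)$chi2, 0)
  expect_equal(pearson_chi2(prop)$p, 1)
  for (seed in 1:5) {
    set.seed(seed)
    tab <- matrix(rpois(4, 30) + 1, 2)
    mine <- pearson_chi2(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("chi-square invariances: row/col swaps and count scaling", {
  set.seed(9)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 25) + 1, 2)
    x2 <- pearson_chi2(tab)$chi2
    expect_equal(pearson_chi2(tab[2:1, ])$chi2, x2, tolerance = 1e-12)
    expect_equal(pearson_chi2(tab[, 2:1])$chi2, x2, tolerance = 1e-12)
    expect_equal(pearson_chi2(t(tab))$chi2, x2, tolerance = 1e-12)
    k <- sample(2:5, 1)
    expect_equal(pearson_chi2(k * tab)$chi2, k * x2, tolerance = 1e-9)
  }
})

test_that("Fisher exact (point-probability rule) matches print and oracle", {
  statins <- matrix(c(5, 6, 147, 352), 2)
  expect_equal(round(fisher_exact(statins), 3), 0.317)
  fibrates <- matrix(c(1, 5, 151, 353), 2)
  expect_equal(round(fisher_exact(fibrates), 3), 0.675)
  expect_equal(fisher_exact(matrix(c(0, 0, 10, 20), 2)), 1)
  for (seed in 1:10) {
    set.seed(seed)
    tab <- matrix(rpois(4, 8), 2)
    mine <- fisher_exact(tab)
    ref <- fisher.test(tab)$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
    expect_equal(fisher_exact(t(tab)), mine, tolerance = 1e-12)
  }
})

test_that("KS statistic equals the brute-force empirical supremum", {
  set.seed(21)
  x <- rnorm(20, 3, 2)
  r <- ks_normality(x)
  xs <- sort(x)
  z <- pnorm((xs - mean(xs)) / sd(xs))
  brute <- max(vapply(seq_along(xs), function(i) {
    max(abs(i / 20 - z[i]), abs((i - 1) / 20 - z[i]))
  }, numeric(1)))
  expect_equal(r$ks_statistic, brute, tolerance = 1e-12)
  # and equals the stats::ks.test statistic on the same reference normal
  ref <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  expect_equal(r$ks_statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("normality screen accepts normal and rejects lognormal samples", {
  hits <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    if (ks_normality(rnorm(1e4))$normal) hits <- hits + 1L
  }
  expect_equal(hits, 5L)
  lp <- lognormal_params(82.9, 65.2)
  set.seed(6)
  tg <- rlnorm(1e4, lp$meanlog, lp$sdlog)
  expect_false(ks_normality(tg)$normal)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("comparison table has the report structure and a clean null", {
  co <- generate_cohort(default_config(seed = 2))
  tab <- compare_table(co)
  expect_equal(nrow(tab), 12L)
  expect_equal(tab$variable[1:3], c("gender_male", "age_onset", "bmi"))
  expect_equal(tab$test[tab$variable == "smoking"], "CHI2")
  expect_equal(tab$test[tab$variable == "statin"], "FISHER_EXACT")
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # duplicated groups: every p value is exactly 1
  g1 <- co[co$group == "GADA_POS", ]
  g2 <- g1
  g2$group <- "T2DM"
  null_tab <- compare_table(as_cohort(rbind(as.data.frame(g1), as.data.frame(g2))))
  expect_true(all(abs(null_tab$p_value - 1) < 1e-12))
  expect_error(compare_table(as_cohort(as.data.frame(g1))), "both groups")
})
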