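# two-group canonical discriminant analysis

test_that("identical groups give a null discriminant", {
  set.seed(1)
  X <- matrix(rnorm(60), 30, 2)
  Xc <- rbind(X, X)
  g <- rep(c("GADA_POS", "T2DM"), each = 30)
  m <- fit_canonical_lda(Xc, g)
  expect_equal(m$eigenvalue, 0, tolerance = 1e-10)
  expect_equal(m$wilks_lambda, 1, tolerance = 1e-10)
  expect_equal(unname(m$loadings), c(0, 0))
})

test_that("single predictor: canonical r is the point-biserial correlation", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- c(rnorm(40, 1), rnorm(60))
    g <- rep(c("GADA_POS", "T2DM"), c(40, 60))
    m <- fit_canonical_lda(matrix(x, ncol = 1), g)
    r <- abs(cor(x, as.numeric(g == "GADA_POS")))
    expect_equal(m$canonical_correlation, r, tolerance = 1e-10)
    expect_equal(m$wilks_lambda, 1 - r^2, tolerance = 1e-10)
  }
})

test_that("algebraic identities hold on random fits", {
  for (seed in 1:8) {
    pr <- gaussian_problem(25 + seed, 40, delta = c(0.8, -0.5, 0.2), seed = seed)
    m <- fit_canonical_lda(pr$X, pr$groups)
    expect_equal(m$wilks_lambda * (1 + m$eigenvalue), 1, tolerance = 1e-10)
    expect_equal(m$canonical_correlation^2,
                 m$eigenvalue / (1 + m$eigenvalue), tolerance = 1e-10)
    expect_true(all(abs(m$loadings) <= 1 + 1e-10))
    expect_equal(sum(m$priors), 1)
    # score normalization and mean separation consistency
    score <- drop(pr$X %*% m$raw_coefficients)
    i1 <- pr$groups == "GADA_POS"
    n1 <- sum(i1); n2 <- sum(!i1); n <- n1 + n2
    sw <- sqrt(((n1 - 1) * var(score[i1]) + (n2 - 1) * var(score[!i1])) / (n - 2))
    expect_equal(sw, 1, tolerance = 1e-10)
    expect_equal((mean(score[i1]) - mean(score[!i1]))^2,
                 m$eigenvalue * n * (n - 2) / (n1 * n2), tolerance = 1e-8)
  }
})

test_that("printed-summary identities: eigenvalue 1.106 implies 0.475 and 0.725", {
  lambda <- 1.106
  expect_equal(round(1 / (1 + lambda), 3), 0.475)
  expect_equal(round(sqrt(lambda / (1 + lambda)), 3), 0.725)
  pub <- published_model()
  expect_equal(round(1 / (1 + pub$eigenvalue), 3), pub$wilks_lambda)
  expect_equal(round(sqrt(pub$eigenvalue / (1 + pub$eigenvalue)), 3),
               pub$canonical_correlation)
})

test_that("fit agrees with the MASS::lda reference on predictions and direction", {
  skip_if_not_installed("MASS")
  for (seed in 1:5) {
    pr <- gaussian_problem(50, 70, delta = c(1, -0.6, 0.3, 0), seed = 100 + seed)
    m <- fit_canonical_lda(pr$X, pr$groups)
    ref <- MASS::lda(pr$X, grouping = pr$groups, prior = c(0.5, 0.5))
    pred_ref <- as.character(predict(ref, pr$X)$class)
    pred_mine <- fisher_classify(m, pr$X)$predicted
    expect_identical(pred_mine, pred_ref)
    # canonical directions proportional
    cors <- abs(cor(drop(pr$X %*% m$raw_coefficients),
                    drop(pr$X %*% ref$scaling)))
    expect_equal(cors, 1, tolerance = 1e-8)
  }
})

test_that("Fisher argmax equals Mahalanobis nearest-centroid with prior offsets", {
  for (seed in 1:6) {
    pr <- gaussian_problem(30, 45, delta = c(0.7, -0.4), seed = 200 + seed)
    priors <- if (seed %% 2) "equal" else "proportional"
    m <- fit_canonical_lda(pr$X, pr$groups, priors = priors)
    pred <- fisher_classify(m, pr$X)$predicted
    Swi <- chol2inv(chol(m$pooled_cov))
    maha <- apply(pr$X, 1, function(x) {
      d1 <- x - m$group_means[, "GADA_POS"]
      d2 <- x - m$group_means[, "T2DM"]
      # smaller penalized Mahalanobis distance wins
      q1 <- drop(t(d1) %*% Swi %*% d1) / 2 - log(m$priors[["GADA_POS"]])
      q2 <- drop(t(d2) %*% Swi %*% d2) / 2 - log(m$priors[["T2DM"]])
      if (q1 < q2) "GADA_POS" else "T2DM"
    })
    expect_identical(pred, unname(maha))
  }
})

test_that("affine rescaling of inputs leaves the invariant quantities unchanged", {
  pr <- gaussian_problem(40, 60, delta = c(1, -0.5, 0.3), seed = 77)
  m0 <- fit_canonical_lda(pr$X, pr$groups)
  X2 <- pr$X
  X2[, 1] <- 100 * X2[, 1] - 7
  X2[, 3] <- -0.2 * X2[, 3] + 3
  m1 <- fit_canonical_lda(X2, pr$groups)
  expect_equal(m1$wilks_lambda, m0$wilks_lambda, tolerance = 1e-10)
  expect_equal(m1$eigenvalue, m0$eigenvalue, tolerance = 1e-9)
  expect_equal(abs(unname(m1$std_coefficients)), abs(unname(m0$std_coefficients)),
               tolerance = 1e-9)
  expect_equal(abs(unname(m1$loadings)), abs(unname(m0$loadings)), tolerance = 1e-9)
  expect_identical(fisher_classify(m1, X2)$predicted,
                   fisher_classify(m0, pr$X)$predicted)
})

test_that("singular within-group covariance names the offending column", {
  set.seed(4)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_canonical_lda(X, rep(c("GADA_POS", "T2DM"), 20)),
               "singular")
  expect_error(fit_canonical_lda(X[, 1:2], rep("CASE", 40)), "unknown group")
})

test_that("loading selection is strict and threshold 0 keeps everything", {
  stub <- structure(list(
    variables = c("a", "b", "c", "d", "e"),
    loadings = c(a = 0.63, b = -0.47, c = 0.43, d = 0.30, e = -0.11)),
    class = "lda_model")
  kept <- select_by_loading(stub, 0.3)
  expect_equal(as.character(kept), c("a", "b", "c"))   # 0.30 dropped: strict >
  expect_named(attr(kept, "dropped"), c("d", "e"))
  expect_equal(as.character(select_by_loading(stub, 0)), stub$variables)
})

test_that("two-stage fit: idempotence, refit loadings, family units", {
  pr <- gaussian_problem(80, 90, delta = c(1.2, -0.9, 0.8), seed = 55)
  ts <- two_stage_fit(pr$X, pr$groups)
  # all loadings above threshold: final fit is the stage-1 fit
  expect_true(all(abs(ts$stage1$loadings) > 0.3))
  expect_identical(ts$model, ts$stage1)

  # add two null columns; they get dropped and the refit changes loadings
  set.seed(56)
  Xn <- cbind(pr$X, n1 = rnorm(170), n2 = rnorm(170))
  ts2 <- two_stage_fit(Xn, pr$groups)
  expect_setequal(ts2$retained, c("v1", "v2", "v3"))
  expect_named(ts2$drop_report, c("n1", "n2"), ignore.order = TRUE)
  expect_false(isTRUE(all.equal(ts2$model$loadings[c("v1", "v2", "v3")],
                                ts2$stage1$loadings[c("v1", "v2", "v3")])))

  # families are retained or dropped as a unit
  fam <- list(f1 = c("v1", "n1"), f2 = c("v2", "v3"), f3 = "n2")
  ts3 <- two_stage_fit(Xn, pr$groups, families = fam)
  expect_setequal(ts3$retained, c("v1", "n1", "v2", "v3"))
})

test_that("planted discriminant direction is recovered with shrinking angle", {
  sigma <- matrix(c(1, 0.3, 0, 0.3, 1, -0.2, 0, -0.2, 1), 3)
  delta <- c(0.8, -0.5, 0.3)
  angles <- sapply(c(400, 6400), function(n) {
    pr <- gaussian_problem(n, n, delta = delta, sigma = sigma, seed = n)
    m <- fit_canonical_lda(pr$X, pr$groups)
    angle_deg(m$raw_coefficients, pr$direction)
  })
  expect_lt(angles[2], 5)
  expect_lt(angles[2], angles[1])
})

test_that("published-coefficient classification matches the hand sums", {
  m <- published_model()
  iv <- setNames(rep(0, 7), m$variables)
  base <- fisher_classify(m, iv)
  expect_equal(base$score_gada, -7.917)
  expect_equal(base$score_t2dm, -3.764)
  expect_equal(base$predicted, "T2DM")
  iv["bmi_lt23"] <- 1
  expect_equal(fisher_classify(m, iv)$delta, -0.494, tolerance = 1e-9)
  iv["hba1c_ge_cut"] <- 1
  r <- fisher_classify(m, iv)
  expect_equal(r$delta, 1.037, tolerance = 1e-9)
  expect_equal(r$predicted, "GADA_POS")
  expect_error(fisher_classify(m, rep(0, 5)), "does not match")
})

test_that("model JSON round-trips and reapplies identically", {
  pr <- gaussian_problem(60, 80, delta = c(1, -0.7), seed = 91)
  m <- fit_canonical_lda(pr$X, pr$groups)
  path <- tempfile(fileext = ".json")
  write_model(m, path, cuts = cutoff_set(100, 9, 50))
  back <- read_model(path)
  expect_equal(back$variables, m$variables)
  expect_equal(back$fisher$coefficients, m$fisher$coefficients,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$wilks_lambda, m$wilks_lambda, tolerance = 1e-12)
  expect_equal(back$cutoffs$tg, 100)
  expect_identical(fisher_classify(back, pr$X)$predicted,
                   fisher_classify(m, pr$X)$predicted)
})
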