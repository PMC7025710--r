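# Shared fixtures: random valid patient records and small Gaussian
# two-group problems with a known discriminant direction.

random_cohort_df <- function(n, seed = NULL, with_group = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    group = if (with_group) sample(c("GADA_POS", "T2DM"), n, replace = TRUE)
            else NA_character_,
    gender = sample(c("M", "F"), n, replace = TRUE),
    age_onset = runif(n, 20, 80),
    bmi = runif(n, 16, 40),
    total_chol = runif(n, 90, 320),
    tg = runif(n, 30, 500),
    hdl = runif(n, 20, 100),
    hba1c = runif(n, 4.5, 16),
    gpt = runif(n, 5, 150),
    creatinine = runif(n, 0.4, 2),
    smoking = sample(c(TRUE, FALSE), n, replace = TRUE),
    statin = sample(c(TRUE, FALSE), n, replace = TRUE),
    fibrate = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Two Gaussian groups sharing covariance `sigma`, mean gap `delta`.
gaussian_problem <- function(n1, n2, delta, sigma = NULL, seed = 1) {
  set.seed(seed)
  p <- length(delta)
  if (is.null(sigma)) sigma <- diag(p)
  L <- chol(sigma)
  X1 <- matrix(rnorm(n1 * p), n1, p) %*% L
  X2 <- sweep(matrix(rnorm(n2 * p), n2, p) %*% L, 2, delta, `+`)
  X <- rbind(X1, X2)
  colnames(X) <- paste0("v", seq_len(p))
  list(X = X,
       groups = rep(c("GADA_POS", "T2DM"), c(n1, n2)),
       # population canonical direction (up to sign/scale)
       direction = solve(sigma, -delta))
}

angle_deg <- function(a, b) {
  cosv <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, cosv)) * 180 / pi
}
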