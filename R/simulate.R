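# Synthetic two-group cohort generator.
#
# Table-style group summaries (mean/SD per continuous variable, bin
# proportions for age and BMI, binary prevalences) are turned into a
# sampling model: Gaussian copula over the continuous block, truncated
# normal marginals with moment-corrected parameters, a moment-matched
# lognormal for triglycerides, independent Bernoulli binaries.

.sim_continuous <- c("age_onset", "bmi", "total_chol", "tg", "hdl",
                     "hba1c", "gpt", "creatinine")
.sim_floors <- c(age_onset = 20, bmi = 0, total_chol = 0, tg = 0,
                 hdl = 0, hba1c = 4, gpt = 0, creatinine = 0)
.age_breaks <- c(20, 30, 50, Inf)
.bmi_breaks <- c(0, 23, 25, Inf)

#' Lognormal parameters matching a target mean and SD
#'
#' Moment matching: `sigma^2 = log(1 + (sd/mean)^2)`,
#' `mu = log(mean) - sigma^2/2`, so the lognormal's analytic mean and SD
#' equal the targets exactly.
#'
#' @param mean,sd Target moments (both > 0).
#' @return List with `meanlog` and `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Moments of a normal(mu, sigma) left-truncated at a.
.trunc_moments <- function(mu, sigma, a) {
  alpha <- (a - mu) / sigma
  lambda <- exp(stats::dnorm(alpha, log = TRUE) -
                  stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 + alpha * lambda - lambda^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Parent (mu, sigma) such that the a-truncated normal has mean m, sd s.
# When the truncated mass under the naive parameters is negligible the
# naive parameters are returned unchanged.
.trunc_solve <- function(m, s, a) {
  if (!is.finite(a) || stats::pnorm(a, m, s) < 1e-8) {
    return(c(mu = m, sigma = s))
  }
  obj <- function(par) {
    mom <- .trunc_moments(par[1], exp(par[2]), a)
    (mom[["mean"]] - m)^2 / s^2 + (mom[["sd"]] - s)^2 / s^2
  }
  fit <- stats::optim(c(m, log(s)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-6) {
    warning(sprintf(
      "truncated-normal moment solve imperfect (floor %.3g, target %.3g +/- %.3g)",
      a, m, s), call. = FALSE)
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Specification of one group's marginal summaries
#'
#' @param n Group size.
#' @param continuous Named list mapping each of `age_onset, bmi, total_chol,
#'   tg, hdl, hba1c, gpt, creatinine` to `c(mean, sd)` in original units.
#' @param tg_lognormal Should triglycerides use a moment-matched lognormal
#'   (the default; TG is strongly right-skewed) rather than a truncated
#'   normal?
#' @param bin_probs Named list with elements `age` and `bmi`, each a
#'   probability vector over the three bins (`[20,30), [30,50), [50,Inf)`
#'   and `(0,23), [23,25), [25,Inf)`).
#' @param binary_prevalence Named vector with elements `male, smoking,
#'   statin, fibrate` in `[0,1]`.
#' @return A `group_spec` object.
#' @export
group_spec <- function(n, continuous, tg_lognormal = TRUE,
                       bin_probs, binary_prevalence) {
  stopifnot(n >= 2)
  miss <- setdiff(.sim_continuous, names(continuous))
  if (length(miss)) stop("continuous spec missing: ", paste(miss, collapse = ", "))
  for (v in .sim_continuous) {
    ms <- continuous[[v]]
    if (length(ms) != 2 || ms[2] <= 0) stop(sprintf("bad (mean, sd) for %s", v))
  }
  for (b in c("age", "bmi")) {
    p <- bin_probs[[b]]
    if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("bin_probs$%s must be 3 nonnegative values summing to 1", b))
    }
  }
  for (v in c("male", "smoking", "statin", "fibrate")) {
    p <- binary_prevalence[[v]]
    if (is.null(p) || p < 0 || p > 1) stop(sprintf("bad prevalence for %s", v))
  }
  structure(list(n = as.integer(n), continuous = continuous,
                 tg_lognormal = isTRUE(tg_lognormal),
                 bin_probs = bin_probs,
                 binary_prevalence = binary_prevalence),
            class = "group_spec")
}

#' Simulation configuration
#'
#' @param gada,t2dm [group_spec()] objects for the case and reference group.
#' @param correlation Latent Gaussian-copula correlation matrix over the
#'   eight continuous variables (order of `.sim_continuous`); must have unit
#'   diagonal and be positive definite.
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @param mode `"MOMENT_MATCH"` targets each variable's printed mean/SD;
#'   `"BIN_CALIBRATED"` additionally draws the age and BMI bins from
#'   `bin_probs` first (bin frequencies then match in expectation) with
#'   values drawn conditional on the bin.
#' @return A `sim_config` object.
#' @export
sim_config <- function(gada, t2dm, correlation = default_correlation(),
                       seed = 1L, mode = c("MOMENT_MATCH", "BIN_CALIBRATED")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gada, "group_spec"), inherits(t2dm, "group_spec"))
  p <- length(.sim_continuous)
  if (!is.matrix(correlation) || any(dim(correlation) != p) ||
      any(abs(diag(correlation) - 1) > 1e-12) ||
      any(abs(correlation - t(correlation)) > 1e-12)) {
    stop("correlation must be a symmetric matrix with unit diagonal over the 8 continuous variables")
  }
  ch <- tryCatch(chol(correlation), error = function(e) NULL)
  if (is.null(ch)) stop("correlation matrix is not positive definite")
  structure(list(gada = gada, t2dm = t2dm, correlation = correlation,
                 seed = as.integer(seed), mode = mode),
            class = "sim_config")
}

#' Default latent correlation matrix
#'
#' The printed group summaries identify only marginals; the default joint
#' structure is an assumption: TG-HDL -0.4, BMI-TG +0.3, BMI-HDL -0.3,
#' all other pairs independent.
#'
#' @return 8x8 correlation matrix over the continuous variables.
#' @export
default_correlation <- function() {
  p <- length(.sim_continuous)
  R <- diag(p)
  dimnames(R) <- list(.sim_continuous, .sim_continuous)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("tg", "hdl", -0.4)
  set_r("bmi", "tg", 0.3)
  set_r("bmi", "hdl", -0.3)
  R
}

#' Default simulation configuration
#'
#' Group sizes 152 (GADA+) and 358 (T2DM) with every mean/SD, age/BMI bin
#' proportion and binary prevalence set to the published cohort's printed
#' summaries. Triglycerides are lognormal (moment-matched). The latent
#' correlations are assumptions, see [default_correlation()].
#'
#' @param seed Integer RNG seed.
#' @param mode See [sim_config()].
#' @return A `sim_config`.
#' @export
default_config <- function(seed = 1L, mode = "MOMENT_MATCH") {
  gada <- group_spec(
    n = 152,
    continuous = list(
      age_onset = c(37.6, 12.6), bmi = c(21.7, 3.8),
      total_chol = c(184.0, 46.9), tg = c(82.9, 65.2), hdl = c(58.0, 18.7),
      hba1c = c(10.5, 3.2), gpt = c(25.1, 18.7), creatinine = c(0.8, 0.2)),
    bin_probs = list(age = c(0.316, 0.493, 0.191),
                     bmi = c(0.750, 0.105, 0.145)),
    binary_prevalence = c(male = 0.487, smoking = 0.217,
                          statin = 0.033, fibrate = 0.007))
  t2dm <- group_spec(
    n = 358,
    continuous = list(
      age_onset = c(50.4, 11.7), bmi = c(26.8, 4.5),
      total_chol = c(194.4, 41.9), tg = c(162.2, 119.9), hdl = c(42.7, 10.5),
      hba1c = c(8.2, 2.3), gpt = c(35.2, 29.2), creatinine = c(0.8, 0.2)),
    bin_probs = list(age = c(0.050, 0.372, 0.578),
                     bmi = c(0.173, 0.196, 0.631)),
    binary_prevalence = c(male = 0.564, smoking = 0.179,
                          statin = 0.017, fibrate = 0.014))
  sim_config(gada, t2dm, seed = seed, mode = mode)
}

# Inverse-CDF through the bin structure: the copula uniform picks the bin
# (cumulative bin probabilities) and the position within it, so bin
# frequencies equal bin_probs in expectation and monotone dependence on the
# latent Gaussian is preserved.
.bin_calibrated_draw <- function(u, probs, breaks, mu, sigma) {
  cum <- c(0, cumsum(probs))
  cum[length(cum)] <- 1
  bin <- findInterval(u, cum, rightmost.closed = TRUE)
  bin[bin < 1] <- 1L
  bin[bin > length(probs)] <- length(probs)
  u_in <- (u - cum[bin]) / pmax(probs[bin], 1e-12)
  u_in <- pmin(pmax(u_in, 1e-12), 1 - 1e-12)
  plo <- stats::pnorm(breaks[bin], mu, sigma)
  phi <- stats::pnorm(breaks[bin + 1], mu, sigma)
  stats::qnorm(plo + u_in * (phi - plo), mu, sigma)
}

.generate_group <- function(spec, correlation, mode, group_label) {
  n <- spec$n
  p <- length(.sim_continuous)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% chol(correlation)
  U <- stats::pnorm(Z)
  colnames(U) <- .sim_continuous
  U <- pmin(pmax(U, 1e-12), 1 - 1e-12)

  vals <- matrix(NA_real_, n, p, dimnames = list(NULL, .sim_continuous))
  for (v in .sim_continuous) {
    ms <- spec$continuous[[v]]
    u <- U[, v]
    if (v == "tg" && spec$tg_lognormal) {
      lp <- lognormal_params(ms[1], ms[2])
      vals[, v] <- stats::qlnorm(u, lp$meanlog, lp$sdlog)
    } else if (mode == "BIN_CALIBRATED" && v == "age_onset") {
      vals[, v] <- .bin_calibrated_draw(u, spec$bin_probs$age, .age_breaks,
                                        ms[1], ms[2])
    } else if (mode == "BIN_CALIBRATED" && v == "bmi") {
      vals[, v] <- .bin_calibrated_draw(u, spec$bin_probs$bmi, .bmi_breaks,
                                        ms[1], ms[2])
    } else {
      a <- .sim_floors[[v]]
      par <- .trunc_solve(ms[1], ms[2], a)
      plo <- stats::pnorm(a, par[["mu"]], par[["sigma"]])
      vals[, v] <- stats::qnorm(plo + u * (1 - plo), par[["mu"]], par[["sigma"]])
    }
  }
  # numeric guard at the floors (inverse CDF can brush the boundary)
  vals[, "age_onset"] <- pmax(vals[, "age_onset"], 20)
  prev <- spec$binary_prevalence
  data.frame(
    group = group_label,
    gender = ifelse(stats::runif(n) < prev[["male"]], "M", "F"),
    as.data.frame(vals),
    smoking = as.integer(stats::runif(n) < prev[["smoking"]]),
    statin = as.integer(stats::runif(n) < prev[["statin"]]),
    fibrate = as.integer(stats::runif(n) < prev[["fibrate"]]),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic two-group cohort
#'
#' Deterministic given `cfg$seed`. Continuous marginals follow the group
#' specs (truncated normal with moment-corrected parameters, or
#' moment-matched lognormal for TG); joint dependence follows the latent
#' Gaussian copula; binaries are independent Bernoulli draws.
#'
#' @param cfg A [sim_config()], e.g. [default_config()].
#' @return A validated `gada_cohort` with `n_gada + n_t2dm` records.
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a sim_config")
  set.seed(cfg$seed)
  df <- rbind(
    .generate_group(cfg$gada, cfg$correlation, cfg$mode, "GADA_POS"),
    .generate_group(cfg$t2dm, cfg$correlation, cfg$mode, "T2DM"))
  prov <- sprintf("synthetic cohort: seed=%d mode=%s n=(%d,%d)",
                  cfg$seed, cfg$mode, cfg$gada$n, cfg$t2dm$n)
  as_cohort(df, provenance = prov)
}
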