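# Two-group canonical linear discriminant analysis.
#
# Two groups admit a closed form: the canonical direction is
# S_w^{-1}(mu1 - mu2), with S_w the pooled within-group covariance on
# n - 2 degrees of freedom. Weights are normalized so the discriminant
# score has unit pooled within-group variance; standardized coefficients,
# structure-matrix loadings, the eigenvalue of S_w^{-1}S_b, Wilks' lambda
# and the canonical correlation all follow from the same decomposition.
# Fisher's per-group classification functions use the same S_w.

.resolve_priors <- function(priors, counts) {
  if (is.character(priors)) {
    priors <- match.arg(priors, c("equal", "proportional"))
    p <- if (priors == "equal") c(0.5, 0.5) else counts / sum(counts)
  } else {
    p <- as.numeric(priors)
    if (length(p) != 2 || any(p <= 0)) stop("priors must be two positive numbers")
    p <- p / sum(p)
  }
  names(p) <- c("GADA_POS", "T2DM")
  p
}

#' Fit a two-group canonical discriminant model
#'
#' All predictors enter simultaneously (enter method). Reported quantities:
#' unstandardized canonical weights (unit pooled within-group score
#' variance), standardized coefficients (weights times pooled within-group
#' SDs), structure-matrix loadings (pooled within-group correlation of each
#' predictor with the score), the eigenvalue of `S_w^{-1} S_b`, Wilks'
#' lambda `1/(1+eigenvalue)` with Bartlett's chi-square test, the canonical
#' correlation, and Fisher's linear classification function per group:
#' `f_g(x) = mu_g' S_w^{-1} x - mu_g' S_w^{-1} mu_g / 2 + log(prior_g)`.
#'
#' @param X Numeric predictor matrix (rows = records); typically the 0/1
#'   indicator matrix from [encode_indicators()].
#' @param groups Group labels (`GADA_POS` / `T2DM`), length `nrow(X)`.
#' @param priors `"equal"` (default), `"proportional"`, or two positive
#'   numbers. Priors shift only the Fisher constants by `log(prior)`.
#' @return Object of class `lda_model`.
#' @export
fit_canonical_lda <- function(X, groups, priors = "equal") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  groups <- as.character(groups)
  if (length(groups) != nrow(X)) stop("groups must match nrow(X)")
  bad <- setdiff(unique(groups), c("GADA_POS", "T2DM"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  i1 <- groups == "GADA_POS"
  n1 <- sum(i1)
  n2 <- sum(!i1)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 members")
  n <- n1 + n2
  p <- ncol(X)

  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu2 <- colMeans(X[!i1, , drop = FALSE])
  S1 <- stats::cov(X[i1, , drop = FALSE])
  S2 <- stats::cov(X[!i1, , drop = FALSE])
  Sw <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n - 2)

  qr_sw <- qr(Sw)
  if (qr_sw$rank < p) {
    culprit <- colnames(X)[qr_sw$pivot[(qr_sw$rank + 1):p]]
    stop("pooled within-group covariance is singular; collinear/constant column(s): ",
         paste(culprit, collapse = ", "))
  }
  Swi <- chol2inv(chol(Sw))
  dimnames(Swi) <- dimnames(Sw)

  d <- mu1 - mu2
  w <- drop(Swi %*% d)
  D2 <- drop(crossprod(d, w))          # Mahalanobis distance^2 between means
  sds <- sqrt(diag(Sw))
  if (D2 > 1e-12) {
    raw <- w / sqrt(D2)                # unit pooled within-group score variance
    std <- raw * sds
    loadings <- drop(Sw %*% raw) / sds # within-group corr(x_j, score)
  } else {
    raw <- std <- loadings <- rep(0, p)
  }
  names(raw) <- names(std) <- names(loadings) <- colnames(X)

  eigenvalue <- (n1 * n2 / (n * (n - 2))) * D2
  wilks <- 1 / (1 + eigenvalue)
  canr <- sqrt(eigenvalue / (1 + eigenvalue))
  # Bartlett's chi-square approximation for the lambda significance test
  chi2 <- -(n - 1 - (p + 2) / 2) * log(wilks)
  wilks_p <- stats::pchisq(chi2, df = p, lower.tail = FALSE)

  pri <- .resolve_priors(priors, c(n1, n2))
  C <- Swi %*% cbind(GADA_POS = mu1, T2DM = mu2)
  consts <- c(GADA_POS = -0.5 * drop(crossprod(mu1, Swi %*% mu1)) + log(pri[[1]]),
              T2DM = -0.5 * drop(crossprod(mu2, Swi %*% mu2)) + log(pri[[2]]))

  structure(list(
    variables = colnames(X),
    raw_coefficients = raw,
    std_coefficients = std,
    loadings = loadings,
    wilks_lambda = wilks,
    eigenvalue = eigenvalue,
    canonical_correlation = canr,
    wilks_chi2 = chi2, wilks_df = p, wilks_p = wilks_p,
    fisher = list(coefficients = C, constants = consts),
    priors = pri,
    group_means = cbind(GADA_POS = mu1, T2DM = mu2),
    pooled_cov = Sw,
    counts = c(GADA_POS = n1, T2DM = n2)),
    class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d predictors, n = (%d, %d)\n",
              length(x$variables), x$counts[1], x$counts[2]))
  cat(sprintf("Wilks' lambda %.3f (chi2 %.1f, df %d, p %.3g); eigenvalue %.3f; canonical r %.3f\n",
              x$wilks_lambda, x$wilks_chi2, x$wilks_df, x$wilks_p,
              x$eigenvalue, x$canonical_correlation))
  tab <- data.frame(std_coef = round(x$std_coefficients, 3),
                    loading = round(x$loadings, 3))
  print(tab)
  invisible(x)
}

#' Retain variables by structure-matrix loading
#'
#' Keeps variables whose absolute loading strictly exceeds `threshold`
#' (default 0.3; a loading of exactly 0.3 in magnitude is dropped).
#'
#' @param model An `lda_model`.
#' @param threshold Absolute-loading retention threshold.
#' @return Character vector of retained variable names, with the dropped
#'   variables and their loadings as attribute `"dropped"`.
#' @export
select_by_loading <- function(model, threshold = 0.3) {
  keep <- abs(model$loadings) > threshold
  retained <- model$variables[keep]
  attr(retained, "dropped") <- model$loadings[!keep]
  retained
}

#' Two-stage enter-method discriminant fit
#'
#' Stage 1 fits all candidate predictors; variables (or whole variable
#' families, when `families` is supplied) whose maximal absolute loading
#' does not exceed `threshold` are dropped; stage 2 refits on the retained
#' set. Note the refit recomputes loadings on the retained set, so stage-2
#' loadings differ from stage-1 loadings.
#'
#' @inheritParams fit_canonical_lda
#' @param threshold Absolute-loading retention threshold (strict `>`).
#' @param families Optional named list grouping column names into families
#'   retained or dropped as units (see [indicator_families()]); columns not
#'   covered by any family form singleton families.
#' @return List of class `lda_two_stage`: `model` (final fit), `stage1`,
#'   `retained` (column names), `drop_report` (named loadings of dropped
#'   columns).
#' @export
two_stage_fit <- function(X, groups, threshold = 0.3, priors = "equal",
                          families = NULL) {
  X <- as.matrix(X)
  stage1 <- fit_canonical_lda(X, groups, priors = priors)
  cols <- stage1$variables
  if (is.null(families)) families <- list()
  covered <- unlist(families, use.names = FALSE)
  for (v in setdiff(cols, covered)) families[[v]] <- v
  families <- lapply(families, intersect, y = cols)
  families <- families[lengths(families) > 0]

  keep_fam <- vapply(families, function(mem) {
    max(abs(stage1$loadings[mem])) > threshold
  }, logical(1))
  retained <- cols[cols %in% unlist(families[keep_fam])]
  dropped <- setdiff(cols, retained)
  if (length(retained) == 0) stop("no variable exceeds the loading threshold")
  final <- if (identical(retained, cols)) stage1 else
    fit_canonical_lda(X[, retained, drop = FALSE], groups, priors = priors)
  structure(list(model = final, stage1 = stage1, retained = retained,
                 drop_report = stage1$loadings[dropped],
                 threshold = threshold),
            class = "lda_two_stage")
}

#' @export
print.lda_two_stage <- function(x, ...) {
  cat(sprintf("<lda_two_stage> retained %d of %d predictors (|loading| > %g)\n",
              length(x$retained), length(x$stage1$variables), x$threshold))
  if (length(x$drop_report)) {
    cat("dropped:", paste(sprintf("%s (%.2f)", names(x$drop_report),
                                  x$drop_report), collapse = ", "), "\n")
  }
  print(x$model)
  invisible(x)
}

#' Classify records with Fisher's linear discriminant functions
#'
#' Computes both group scores for each record and assigns the group with
#' the larger score; an exact tie is assigned to T2DM (the clinical
#' default for the reference group).
#'
#' @param model An `lda_model` (or a model artifact from [read_model()] /
#'   [published_model()]) supplying the per-group Fisher functions.
#' @param iv Indicator matrix (or single vector) with columns aligned to
#'   `model$variables`.
#' @return Data frame with `score_gada`, `score_t2dm`, `delta`
#'   (`score_gada - score_t2dm`) and `predicted`.
#' @export
fisher_classify <- function(model, iv) {
  if (is.null(dim(iv))) iv <- matrix(iv, nrow = 1,
                                     dimnames = list(NULL, names(iv)))
  iv <- as.matrix(iv)
  p <- length(model$variables)
  if (ncol(iv) != p) {
    stop(sprintf("indicator length %d does not match the %d model variables",
                 ncol(iv), p))
  }
  if (!is.null(colnames(iv)) && !identical(colnames(iv), model$variables)) {
    if (!all(model$variables %in% colnames(iv))) {
      stop("indicator columns do not match model variables: expected ",
           paste(model$variables, collapse = ", "))
    }
    iv <- iv[, model$variables, drop = FALSE]
  }
  scores <- iv %*% model$fisher$coefficients
  scores <- sweep(scores, 2, model$fisher$constants, `+`)
  delta <- scores[, "GADA_POS"] - scores[, "T2DM"]
  data.frame(score_gada = scores[, "GADA_POS"],
             score_t2dm = scores[, "T2DM"],
             delta = delta,
             predicted = ifelse(delta > 0, "GADA_POS", "T2DM"),
             stringsAsFactors = FALSE)
}
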