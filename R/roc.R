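# Empirical ROC curves and closest-to-corner cutpoint selection.

#' Empirical ROC curve
#'
#' Thresholds are the distinct observed values (no interpolation). With
#' `direction = "CASE_HIGH"` a record tests positive when its value is
#' `>= threshold`; with `"CASE_LOW"` when it is `< threshold`. The AUC is
#' the rank-based (Mann-Whitney) estimate with ties counted one half; its
#' 95% CI uses the Hanley-McNeil standard error.
#'
#' @param values Numeric marker values.
#' @param is_case Logical vector, `TRUE` for cases (GADA+).
#' @param direction `"CASE_HIGH"`, `"CASE_LOW"`, or `NULL` to infer from
#'   the sign of the case-minus-control mean difference.
#' @param variable Optional name carried into the result.
#' @return Object of class `roc_curve`: `variable`, `direction`, `points`
#'   (data frame `threshold`, `sensitivity`, `specificity`), `auc`,
#'   `auc_ci`.
#' @export
empirical_roc <- function(values, is_case, direction = NULL,
                          variable = NA_character_) {
  keep <- !is.na(values) & !is.na(is_case)
  values <- values[keep]
  is_case <- as.logical(is_case[keep])
  n1 <- as.numeric(sum(is_case))
  n0 <- as.numeric(sum(!is_case))
  if (n1 == 0 || n0 == 0) stop("empirical_roc: need at least one case and one control")
  if (is.null(direction)) {
    direction <- if (mean(values[is_case]) >= mean(values[!is_case]))
      "CASE_HIGH" else "CASE_LOW"
  }
  direction <- match.arg(direction, c("CASE_HIGH", "CASE_LOW"))

  thr <- sort(unique(values))
  idx <- match(values, thr)
  case_at <- tabulate(idx[is_case], nbins = length(thr))
  ctrl_at <- tabulate(idx[!is_case], nbins = length(thr))
  cases_lt <- cumsum(case_at) - case_at   # count strictly below each threshold
  ctrls_lt <- cumsum(ctrl_at) - ctrl_at
  if (direction == "CASE_HIGH") {
    sens <- (n1 - cases_lt) / n1
    spec <- ctrls_lt / n0
    w <- values
  } else {
    sens <- cases_lt / n1
    spec <- (n0 - ctrls_lt) / n0
    w <- -values
  }
  # Mann-Whitney AUC with ties counted 1/2, via midranks
  r <- rank(w, ties.method = "average")
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))

  structure(list(variable = variable, direction = direction,
                 points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, auc_ci = ci, n_case = n1, n_control = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %s (%s): AUC %.3f (95%% CI %.3f-%.3f), %d points\n",
              x$variable, x$direction, x$auc, x$auc_ci[1], x$auc_ci[2],
              nrow(x$points)))
  invisible(x)
}

#' Closest-to-corner ROC cutpoint
#'
#' Selects the ROC point minimizing the distance to the upper-left corner,
#' `sqrt((1 - sensitivity)^2 + (1 - specificity)^2)`. Ties are broken
#' toward higher sensitivity, then lower threshold. Both the distance and
#' its square are reported (published "minimum distance" columns often
#' print the squared form).
#'
#' @param curve A [empirical_roc()] result.
#' @return Object of class `roc_cutoff`: `variable`, `cutoff`,
#'   `sensitivity`, `specificity`, `distance`, `distance_squared`, `rule`.
#' @export
min_distance_cutoff <- function(curve) {
  pts <- curve$points
  if (nrow(pts) == 0) stop("min_distance_cutoff: empty curve")
  d2 <- (1 - pts$sensitivity)^2 + (1 - pts$specificity)^2
  best <- which(d2 <= min(d2) + 1e-12)
  if (length(best) > 1) {
    best <- best[order(-pts$sensitivity[best], pts$threshold[best])]
  }
  i <- best[1]
  op <- if (curve$direction == "CASE_HIGH") ">=" else "<"
  structure(list(variable = curve$variable,
                 cutoff = pts$threshold[i],
                 sensitivity = pts$sensitivity[i],
                 specificity = pts$specificity[i],
                 distance = sqrt(d2[i]),
                 distance_squared = d2[i],
                 rule = sprintf("%s %s %g", curve$variable, op, pts$threshold[i]),
                 auc = curve$auc, auc_ci = curve$auc_ci),
            class = "roc_cutoff")
}

#' @export
print.roc_cutoff <- function(x, ...) {
  cat(sprintf("<roc_cutoff> %s: sens %.3f spec %.3f dist %.3f (d^2 %.3f) AUC %.3f\n",
              x$rule, x$sensitivity, x$specificity, x$distance,
              x$distance_squared, x$auc))
  invisible(x)
}

#' ROC cutpoints for a set of cohort variables
#'
#' Runs [empirical_roc()] (direction inferred from group means) and
#' [min_distance_cutoff()] per variable, with GADA+ as the case group.
#' Returns the per-variable cutoff results plus a [cutoff_set()] built
#' from the TG/HbA1c/HDL cutpoints for downstream indicator encoding.
#'
#' @param cohort A labeled `gada_cohort`.
#' @param variables Cohort column names to analyze (default: the five labs
#'   screened in the derivation pipeline).
#' @return List with `results` (named list of `roc_cutoff`) and `cuts`
#'   (a `cutoff_set`, present when TG/HbA1c/HDL are all analyzed).
#' @export
cutoffs_for_variables <- function(cohort,
                                  variables = c("hba1c", "total_chol", "hdl",
                                                "tg", "gpt")) {
  is_case <- cohort$group == "GADA_POS"
  results <- lapply(variables, function(v) {
    min_distance_cutoff(empirical_roc(cohort[[v]], is_case, variable = v))
  })
  names(results) <- variables
  cuts <- NULL
  if (all(c("tg", "hba1c", "hdl") %in% variables)) {
    cuts <- cutoff_set(tg = results$tg$cutoff,
                       hba1c = results$hba1c$cutoff,
                       hdl = results$hdl$cutoff)
  }
  list(results = results, cuts = cuts)
}
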