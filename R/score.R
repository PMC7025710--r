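# Applying a discriminant model to cohorts and summarizing accuracy.

#' Score a cohort with a discriminant model
#'
#' Encodes each record's indicators with the model's cutoffs and applies
#' the Fisher classification functions. Records missing any needed field
#' are reported (attribute `"skipped"`) and not scored.
#'
#' @param model An `lda_model` fitted on the seven standard indicators, or
#'   a model artifact from [read_model()] / [published_model()].
#' @param cohort A `gada_cohort` (group labels optional).
#' @param cuts Cutoffs for indicator encoding; defaults to the model's own
#'   `cutoffs` when present, else [cutoff_set()].
#' @return Data frame with one row per scored record: `score_gada`,
#'   `score_t2dm`, `delta`, `predicted`, plus `group` when labels exist.
#' @export
score_cohort <- function(model, cohort, cuts = NULL) {
  if (nrow(cohort) == 0) stop("score_cohort: empty cohort")
  if (is.null(cuts)) cuts <- model$cutoffs %||% cutoff_set()
  needed <- c("age_onset", "bmi", "tg", "hba1c", "hdl")
  complete <- !Reduce(`|`, lapply(cohort[needed], is.na), rep(FALSE, nrow(cohort)))
  skipped <- which(!complete)
  scored <- cohort[complete, , drop = FALSE]
  if (nrow(scored) == 0) stop("score_cohort: no record has all five variable families")
  iv <- encode_indicators(scored, cuts)
  out <- fisher_classify(model, iv)
  if (!all(is.na(scored$group))) out$group <- scored$group
  attr(out, "skipped") <- skipped
  if (length(skipped)) {
    warning(sprintf("%d record(s) skipped for missing fields", length(skipped)),
            call. = FALSE)
  }
  out
}

#' Confusion summary for predicted vs true groups
#'
#' GADA+ is the positive class throughout: `sensitivity = tp / (tp + fn)`
#' is the detection rate among GADA+ records and
#' `specificity = tn / (fp + tn)` among T2DM records. Proportions are
#' stored unrounded; rounding belongs to report rendering only.
#'
#' @param predictions,truths Aligned vectors of `GADA_POS` / `T2DM`.
#' @return Object of class `confusion_summary` with counts `tp, fn, fp,
#'   tn` and `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate <- function(predictions, truths) {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (length(predictions) != length(truths)) {
    stop("evaluate: predictions and truths must have equal length")
  }
  ok <- c("GADA_POS", "T2DM")
  bad <- setdiff(unique(c(predictions, truths)), c(ok, NA))
  if (length(bad)) stop("evaluate: unknown label(s): ", paste(bad, collapse = ", "))
  keep <- !is.na(predictions) & !is.na(truths)
  predictions <- predictions[keep]
  truths <- truths[keep]
  tp <- sum(predictions == "GADA_POS" & truths == "GADA_POS")
  fn <- sum(predictions == "T2DM" & truths == "GADA_POS")
  fp <- sum(predictions == "GADA_POS" & truths == "T2DM")
  tn <- sum(predictions == "T2DM" & truths == "T2DM")
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 accuracy = (tp + tn) / (tp + fn + fp + tn),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (fp + tn)),
            class = "confusion_summary")
}

#' Build a confusion summary directly from the four counts
#'
#' @param tp,fn,fp,tn Classification counts with GADA+ positive.
#' @return A `confusion_summary`.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  evaluate(c(rep("GADA_POS", tp), rep("T2DM", fn),
             rep("GADA_POS", fp), rep("T2DM", tn)),
           c(rep("GADA_POS", tp + fn), rep("T2DM", fp + tn)))
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary> (rows = truth, cols = predicted; GADA+ positive)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(c("GADA_POS", "T2DM"), c("GADA_POS", "T2DM")))
  print(m)
  cat(sprintf("accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
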