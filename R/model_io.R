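# JSON serialization of discriminant models and the packaged published
# coefficient artifact.

#' Serialize a discriminant model to JSON
#'
#' Writes every `lda_model` field needed to re-apply the tool (Fisher
#' functions, variables) alongside the descriptive quantities
#' (standardized coefficients, loadings, Wilks' lambda, eigenvalue,
#' canonical correlation) and the lab cutoffs used for indicator encoding.
#'
#' @param model An `lda_model`.
#' @param path Output path.
#' @param cuts The [cutoff_set()] used to encode the model's indicators.
#' @param provenance Free text recorded in the artifact.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, cuts = cutoff_set(),
                        provenance = "fitted model") {
  art <- list(
    format = "gadadiscrim-model/1",
    provenance = provenance,
    variables = model$variables,
    raw_coefficients = as.list(model$raw_coefficients),
    std_coefficients = as.list(model$std_coefficients),
    loadings = as.list(model$loadings),
    wilks_lambda = model$wilks_lambda,
    eigenvalue = model$eigenvalue,
    canonical_correlation = model$canonical_correlation,
    wilks_chi2 = model$wilks_chi2, wilks_df = model$wilks_df,
    wilks_p = model$wilks_p,
    priors = as.list(model$priors),
    fisher = list(
      GADA_POS = list(coefficients = unname(model$fisher$coefficients[, "GADA_POS"]),
                      constant = unname(model$fisher$constants[["GADA_POS"]])),
      T2DM = list(coefficients = unname(model$fisher$coefficients[, "T2DM"]),
                  constant = unname(model$fisher$constants[["T2DM"]]))),
    cutoffs = list(tg = cuts$tg, hba1c = cuts$hba1c, hdl = cuts$hdl))
  jsonlite::write_json(art, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a discriminant model artifact
#'
#' @param path Path to a JSON artifact written by [write_model()] (or the
#'   packaged published artifact).
#' @return List of class `lda_model` usable by [fisher_classify()] and
#'   [score_cohort()]; includes `cutoffs` as a [cutoff_set()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model artifact not found: %s", path))
  art <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(art$format, "gadadiscrim-model/1")) {
    stop("not a gadadiscrim model artifact: ", path)
  }
  vars <- art$variables
  coefs <- cbind(GADA_POS = as.numeric(art$fisher$GADA_POS$coefficients),
                 T2DM = as.numeric(art$fisher$T2DM$coefficients))
  rownames(coefs) <- vars
  num_or_null <- function(x) if (is.null(x)) NULL else {
    v <- unlist(x)
    if (!is.null(names(v))) v <- v[vars]
    as.numeric(v)
  }
  named <- function(x) if (is.null(x)) NULL else stats::setNames(x, vars)
  structure(list(
    variables = vars,
    raw_coefficients = named(num_or_null(art$raw_coefficients)),
    std_coefficients = named(num_or_null(art$std_coefficients)),
    loadings = named(num_or_null(art$loadings)),
    wilks_lambda = art$wilks_lambda,
    eigenvalue = art$eigenvalue,
    canonical_correlation = art$canonical_correlation,
    wilks_chi2 = art$wilks_chi2, wilks_df = art$wilks_df,
    wilks_p = art$wilks_p,
    priors = unlist(art$priors),
    fisher = list(coefficients = coefs,
                  constants = c(GADA_POS = art$fisher$GADA_POS$constant,
                                T2DM = art$fisher$T2DM$constant)),
    counts = c(GADA_POS = NA_integer_, T2DM = NA_integer_),
    cutoffs = cutoff_set(tg = art$cutoffs$tg, hba1c = art$cutoffs$hba1c,
                         hdl = art$cutoffs$hdl),
    provenance = art$provenance),
    class = "lda_model")
}

#' The published discriminant tool
#'
#' Loads the packaged artifact holding the published Fisher classification
#' coefficients over the seven indicators (age/BMI bins plus the
#' TG >= 98 mg/dL, HbA1c >= 8.6 %, HDL-C >= 46 mg/dL indicators), the
#' published standardized coefficients, loadings, Wilks' lambda 0.475,
#' eigenvalue 1.106 and canonical correlation 0.725.
#'
#' @return An `lda_model` artifact (see [read_model()]).
#' @export
published_model <- function() {
  read_model(system.file("extdata", "published_model.json",
                         package = "gadadiscrim", mustWork = TRUE))
}
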