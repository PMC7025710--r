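# Patient-record container, CSV I/O, validation and indicator encoding.

#' Canonical cohort column names
#'
#' The tabular schema used throughout the package. `group` and the two
#' gender/boolean habit columns are categorical; everything else is numeric
#' in the units of routine diabetes care (mg/dL for lipids, percent for
#' HbA1c, U/L for GPT, years for age at onset, kg/m^2 for BMI).
#'
#' @return Character vector of the thirteen canonical column names.
#' @export
cohort_columns <- function() {
  c("group", "gender", "age_onset", "bmi", "total_chol", "tg", "hdl",
    "hba1c", "gpt", "creatinine", "smoking", "statin", "fibrate")
}

.numeric_cols <- c("age_onset", "bmi", "total_chol", "tg", "hdl",
                   "hba1c", "gpt", "creatinine")
.bool_cols <- c("smoking", "statin", "fibrate")
.groups <- c("GADA_POS", "T2DM")

#' Body mass index
#'
#' Weight in kilograms divided by the square of height in meters.
#'
#' @param weight_kg Body weight, kg. Must be strictly positive.
#' @param height_m Height, m. Must be strictly positive.
#' @return BMI in kg/m^2 (vectorized).
#' @examples
#' compute_bmi(70, 1.75)
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_m)) ||
      any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("compute_bmi: weight_kg and height_m must be finite and strictly positive")
  }
  weight_kg / height_m^2
}

#' Cutoff set for the binary lab indicators
#'
#' Defaults are the ROC-derived cutpoints used by the published tool:
#' TG 98 mg/dL, HbA1c 8.6 %, HDL-C 46 mg/dL. All three indicators are coded
#' as `value >= cutoff`; the discriminant coefficients absorb orientation.
#'
#' @param tg,hba1c,hdl Cutoff values in original units.
#' @return An object of class `cutoff_set`.
#' @export
cutoff_set <- function(tg = 98, hba1c = 8.6, hdl = 46) {
  stopifnot(is.numeric(tg), is.numeric(hba1c), is.numeric(hdl),
            length(tg) == 1, length(hba1c) == 1, length(hdl) == 1)
  structure(list(tg = tg, hba1c = hba1c, hdl = hdl), class = "cutoff_set")
}

.parse_bool <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    out <- rep(NA, length(x))
    out[x == 1] <- TRUE
    out[x == 0] <- FALSE
    return(out)
  }
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "t", "y", "yes")] <- TRUE
  out[s %in% c("0", "false", "f", "n", "no")] <- FALSE
  out
}

.parse_group <- function(x) {
  s <- toupper(trimws(as.character(x)))
  s[s %in% c("GADA_POS", "GADA+", "GADA", "CASE")] <- "GADA_POS"
  s[s %in% c("T2DM", "T2D", "REFERENCE", "CONTROL")] <- "T2DM"
  s[!(s %in% .groups)] <- NA_character_
  s
}

#' Coerce and validate a data frame as a cohort
#'
#' Enforces the record invariants: `age_onset >= 20` (the tool targets
#' adult-onset diabetes), strictly positive laboratory values and BMI, and
#' a parseable group label where one is present (`group` may be `NA` for
#' scoring-only records). Rows violating an invariant are dropped with a
#' row-indexed warning; rows with missing analysis variables are dropped as
#' incomplete (complete-case convention). A validation report is attached
#' as attribute `"validation"`.
#'
#' @param df A data frame holding (at least) the columns of
#'   [cohort_columns()], possibly under other names via `schema`.
#' @param schema Optional named character vector mapping canonical names to
#'   the names used in `df`, e.g. `c(hba1c = "A1C")`.
#' @param provenance Free-text origin recorded on the object.
#' @return A `gada_cohort` data frame.
#' @export
as_cohort <- function(df, schema = NULL, provenance = "in-memory data frame") {
  if (!is.data.frame(df)) stop("as_cohort: `df` must be a data.frame")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) stop(sprintf("schema column '%s' (for '%s') not found", src, canon))
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- df[cohort_columns()]
  n_input <- nrow(df)

  out <- data.frame(row.names = NULL)
  out <- df
  out$group <- .parse_group(df$group)
  g <- toupper(trimws(as.character(df$gender)))
  g[g %in% c("M", "MALE", "MEN")] <- "M"
  g[g %in% c("F", "FEMALE", "WOMEN")] <- "F"
  g[!(g %in% c("M", "F"))] <- NA_character_
  out$gender <- g
  row_errors <- list()
  for (col in .numeric_cols) {
    v <- if (is.numeric(df[[col]])) df[[col]] else
      suppressWarnings(as.numeric(as.character(df[[col]])))
    bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(v))
    for (i in bad) {
      row_errors[[length(row_errors) + 1L]] <-
        data.frame(row = i, field = col, message = "unparseable numeric")
    }
    out[[col]] <- v
  }
  for (col in .bool_cols) out[[col]] <- .parse_bool(df[[col]])

  # invariant violations (explicit bad values, not missingness)
  invalid <- rep(FALSE, n_input)
  flag <- function(idx, field, msg) {
    for (i in idx) {
      row_errors[[length(row_errors) + 1L]] <<-
        data.frame(row = i, field = field, message = msg)
    }
    invalid[idx] <<- TRUE
  }
  flag(which(!is.na(out$age_onset) & out$age_onset < 20), "age_onset",
       "age at onset below 20 years")
  for (col in c("bmi", "total_chol", "tg", "hdl", "hba1c", "gpt", "creatinine")) {
    flag(which(!is.na(out[[col]]) & out[[col]] <= 0), col, "non-positive value")
  }
  bad_group <- which(is.na(out$group) & !is.na(df$group) &
                       trimws(as.character(df$group)) != "")
  flag(bad_group, "group", "unrecognized group label")

  analysis_cols <- c("gender", .numeric_cols, .bool_cols)
  incomplete <- !invalid &
    Reduce(`|`, lapply(out[analysis_cols], is.na), rep(FALSE, n_input))
  keep <- !invalid & !incomplete
  n_invalid <- sum(invalid)
  n_incomplete <- sum(incomplete)
  if (n_invalid > 0) {
    warning(sprintf("dropped %d row(s) violating record invariants (rows %s)",
                    n_invalid, paste(which(invalid), collapse = ", ")),
            call. = FALSE)
  }
  if (n_incomplete > 0) {
    message(sprintf("complete-case filter: dropped %d incomplete row(s)", n_incomplete))
  }
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  report <- list(
    n_input = n_input, n_kept = nrow(res),
    n_dropped_invalid = n_invalid, n_dropped_incomplete = n_incomplete,
    row_errors = if (length(row_errors)) do.call(rbind, row_errors)
                 else data.frame(row = integer(), field = character(), message = character())
  )
  structure(res,
            class = c("gada_cohort", "data.frame"),
            provenance = provenance,
            validation = report)
}

#' Read a cohort from CSV
#'
#' Comma-separated, header row required, UTF-8, decimal point. Booleans are
#' accepted as 0/1, true/false, T/F, Y/N, yes/no (case-insensitive).
#'
#' @inheritParams as_cohort
#' @param path Path to the CSV file.
#' @return A validated `gada_cohort`; see [as_cohort()] for the dropping
#'   rules and the attached validation report.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  as_cohort(df, schema = schema, provenance = normalizePath(path))
}

#' Write a cohort to CSV
#'
#' Numeric fields are written with 17 significant digits so that a
#' write/read round trip reproduces every double exactly.
#'
#' @param cohort A `gada_cohort` (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (col in .numeric_cols) {
    df[[col]] <- vapply(df[[col]], function(v) {
      if (is.na(v)) "" else sprintf("%.17g", v)
    }, character(1))
  }
  for (col in .bool_cols) df[[col]] <- as.integer(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.gada_cohort <- function(x, ...) {
  grp <- table(factor(x$group, levels = .groups), useNA = "ifany")
  cat(sprintf("<gada_cohort> %d records (GADA_POS %d, T2DM %d)\n",
              nrow(x), grp[["GADA_POS"]], grp[["T2DM"]]))
  cat("provenance:", attr(x, "provenance") %||% "unknown", "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode the seven discriminant indicators
#'
#' Dummy coding used by the discriminant tool. Age bins are `[20,30)`,
#' `[30,50)`, `[50,Inf)` and BMI bins `(0,23)`, `[23,25)`, `[25,Inf)`;
#' the oldest/heaviest bin is the reference level and carries no dummy.
#' The three lab indicators are `value >= cutoff` (inclusive).
#'
#' @param x A `gada_cohort`, data frame, or single-record list with fields
#'   `age_onset`, `bmi`, `tg`, `hba1c`, `hdl`.
#' @param cuts A [cutoff_set()].
#' @return Integer 0/1 matrix with one row per record and columns
#'   `age_lt30, age_30to50, bmi_lt23, bmi_23to25, tg_ge_cut, hba1c_ge_cut,
#'   hdl_ge_cut`.
#' @export
encode_indicators <- function(x, cuts = cutoff_set()) {
  if (!inherits(cuts, "cutoff_set")) stop("`cuts` must be a cutoff_set")
  if (!is.data.frame(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  needed <- c("age_onset", "bmi", "tg", "hba1c", "hdl")
  for (f in needed) {
    if (is.null(x[[f]])) stop(sprintf("encode_indicators: missing field '%s'", f))
  }
  iv <- cbind(
    age_lt30     = as.integer(x$age_onset < 30),
    age_30to50   = as.integer(x$age_onset >= 30 & x$age_onset < 50),
    bmi_lt23     = as.integer(x$bmi < 23),
    bmi_23to25   = as.integer(x$bmi >= 23 & x$bmi < 25),
    tg_ge_cut    = as.integer(x$tg >= cuts$tg),
    hba1c_ge_cut = as.integer(x$hba1c >= cuts$hba1c),
    hdl_ge_cut   = as.integer(x$hdl >= cuts$hdl)
  )
  rownames(iv) <- NULL
  iv
}

#' Indicator families
#'
#' Grouping of the indicator columns into clinical variable families, used
#' when loading-based selection retains or drops a family as a unit.
#'
#' @return Named list mapping family name to its indicator column names.
#' @export
indicator_families <- function() {
  list(age = c("age_lt30", "age_30to50"),
       bmi = c("bmi_lt23", "bmi_23to25"),
       tg = "tg_ge_cut",
       hba1c = "hba1c_ge_cut",
       hdl = "hdl_ge_cut")
}
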