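#' Missing-value imputation
#'
#' Missing cells are filled before any statistics or equalization, with a
#' rule per variable kind. Categorical variables always receive their mode
#' (ties broken by the lexicographically smallest category), which preserves
#' the variable's modal structure. Continuous variables are imputed only
#' when less than half the values are missing: a Shapiro-Wilk check on the
#' observed values decides between the mean (normal-looking, p > 0.05) and
#' the median (otherwise). Variables at or above 50% missingness are left
#' untouched and flagged.
#'
#' @name imputation
NULL

new_imputation_record <- function(variable, method, n_imputed, fill_value,
                                  missing_fraction, flag = NA_character_) {
  structure(list(variable = variable, method = method, n_imputed = n_imputed,
                 fill_value = fill_value, missing_fraction = missing_fraction,
                 flag = flag),
            class = "imputation_record")
}

#' @export
print.imputation_record <- function(x, ...) {
  cat(sprintf("<imputation_record> %s: method=%s, %d filled (%.1f%% missing)%s\n",
              x$variable, x$method, x$n_imputed, 100 * x$missing_fraction,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Impute a categorical variable with its mode
#'
#' @param values character vector (missing as `NA`)
#' @param variable variable name recorded in the log entry
#' @return list with `values` (filled vector) and `record`
#'   (an `imputation_record`)
#' @export
impute_categorical <- function(values, variable = "variable") {
  obs <- values[!is.na(values)]
  if (length(obs) == 0L)
    cohorteq_error("cohorteq_all_missing",
                   paste0("cannot impute all-missing variable: ", variable))
  n_missing <- sum(is.na(values))
  frac <- n_missing / length(values)
  if (n_missing == 0L)
    return(list(values = values,
                record = new_imputation_record(variable, "none", 0L, NA, frac)))
  counts <- table(obs)
  # ties: smallest category in lexicographic order (table() sorts its names)
  mode_cat <- names(counts)[which.max(counts)]
  values[is.na(values)] <- mode_cat
  list(values = values,
       record = new_imputation_record(variable, "mode", n_missing, mode_cat, frac))
}

#' Impute a continuous variable with mean or median
#'
#' The observed values are tested with Shapiro-Wilk; p > 0.05 selects the
#' mean, otherwise the median. Fewer than 3 observed values leave the
#' normality test undefined, so the median is used and the record flagged.
#' At 50% missingness or more the variable is left unimputed
#' (`method = "none"`, flagged).
#'
#' @param values numeric vector (missing as `NA`)
#' @param variable variable name recorded in the log entry
#' @return list with `values` and `record`; `values` keeps its `NA`s when the
#'   variable is skipped
#' @export
impute_continuous <- function(values, variable = "variable") {
  stopifnot(is.numeric(values))
  n_missing <- sum(is.na(values))
  frac <- n_missing / length(values)
  obs <- values[!is.na(values)]
  if (length(obs) == 0L)
    cohorteq_error("cohorteq_all_missing",
                   paste0("cannot impute all-missing variable: ", variable))
  if (n_missing == 0L)
    return(list(values = values,
                record = new_imputation_record(variable, "none", 0L, NA_real_, frac)))
  if (frac >= 0.5)
    return(list(values = values,
                record = new_imputation_record(variable, "none", 0L, NA_real_, frac,
                                               flag = "skipped: >=50% missing")))
  if (length(obs) < 3L) {
    fill <- stats::median(obs)
    values[is.na(values)] <- fill
    return(list(values = values,
                record = new_imputation_record(variable, "median", n_missing, fill,
                                               frac, flag = "normality test undefined (n < 3)")))
  }
  sw_p <- if (stats::sd(obs) == 0) 0 else shapiro_wilk(obs)$p
  if (sw_p > 0.05) {
    fill <- mean(obs)
    method <- "mean"
  } else {
    fill <- stats::median(obs)
    method <- "median"
  }
  values[is.na(values)] <- fill
  list(values = values,
       record = new_imputation_record(variable, method, n_missing, fill, frac))
}

#' Quantify missingness per variable
#'
#' @param table a [cohort_table()]
#' @return data.frame with one row per non-identifier variable: `variable`,
#'   `n_missing`, `missing_fraction`
#' @export
missingness_summary <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  vars <- setdiff(names(table$data), table$id_column)
  n <- nrow(table$data)
  out <- data.frame(
    variable = vars,
    n_missing = vapply(vars, function(v) sum(is.na(table$data[[v]])), integer(1)),
    stringsAsFactors = FALSE)
  out$missing_fraction <- out$n_missing / n
  rownames(out) <- NULL
  out
}

#' Impute every feature variable of a cohort table
#'
#' Applies [impute_categorical()] / [impute_continuous()] to each feature
#' column according to its inferred kind; identifier and target columns are
#' never imputed. Cells filled for continuous variables are written back in
#' full precision.
#'
#' @param table a [cohort_table()] with roles assigned
#' @param specs variable specs from [infer_variable_types()] (recomputed if
#'   omitted)
#' @return list with `table` (imputed) and `log` (list of
#'   `imputation_record`s, one per feature variable with any missing cells)
#' @export
impute_cohort <- function(table, specs = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  specs <- specs %||% infer_variable_types(table)
  log <- list()
  for (nm in names(table$data)) {
    spec <- specs[[nm]]
    if (spec$role != "feature" || spec$n_missing == 0L) next
    col <- table$data[[nm]]
    if (spec$kind == "categorical") {
      res <- impute_categorical(col, nm)
      table$data[[nm]] <- res$values
    } else {
      res <- impute_continuous(parse_number(col), nm)
      filled <- ifelse(is.na(res$values), NA_character_,
                       format(res$values, digits = 15, trim = TRUE, scientific = FALSE))
      # keep original text for cells that were already present
      filled[!is.na(col)] <- col[!is.na(col)]
      table$data[[nm]] <- filled
    }
    log[[nm]] <- res$record
  }
  list(table = table, log = log)
}
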