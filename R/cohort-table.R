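#' Cohort tables
#'
#' A `cohort_table` is the package's central container: a rectangular
#' samples-by-variables table in which every cell is text, a number (stored
#' as its text representation), or missing (`NA`). Two columns can carry
#' roles: a unique-identifier column and a target (grouping) column whose
#' values define the subpopulations to compare and balance.
#'
#' @param data data.frame of character columns (missing cells as `NA`)
#' @param id_column,target_column optional column names carrying the
#'   identifier / target role (assigned by [validate_roles()])
#' @return an object of class `cohort_table`
#' @seealso [load_table()], [validate_roles()], [infer_variable_types()]
#' @export
cohort_table <- function(data, id_column = NULL, target_column = NULL) {
  stopifnot(is.data.frame(data))
  if (anyDuplicated(names(data)))
    cohorteq_error("cohorteq_duplicate_columns",
                   paste0("duplicate column names: ",
                          paste(unique(names(data)[duplicated(names(data))]),
                                collapse = ", ")))
  data[] <- lapply(data, function(col) normalize_missing(as.character(col)))
  rownames(data) <- NULL
  structure(list(data = data,
                 id_column = id_column,
                 target_column = target_column),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d samples x %d variables\n",
              nrow(x$data), ncol(x$data)))
  if (!is.null(x$id_column))
    cat("  identifier:", x$id_column, "\n")
  if (!is.null(x$target_column)) {
    tab <- table(x$data[[x$target_column]])
    cat(sprintf("  target: %s (%s)\n", x$target_column,
                paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$data)

#' Numbers of samples and variables
#' @param table a [cohort_table()]
#' @return integer count
#' @export
n_samples <- function(table) nrow(table$data)

#' @rdname n_samples
#' @export
n_variables <- function(table) ncol(table$data)

#' Identifier values of a cohort table
#' @param table a [cohort_table()] with roles assigned
#' @return character vector of identifiers, in row order
#' @export
sample_ids <- function(table) {
  if (is.null(table$id_column))
    cohorteq_error("cohorteq_no_roles", "identifier role not assigned yet")
  table$data[[table$id_column]]
}

#' Subset a cohort table to a set of identifiers
#' @param table a [cohort_table()] with roles assigned
#' @param ids identifiers to keep
#' @return a `cohort_table` with the matching rows, in original row order
#' @export
subset_ids <- function(table, ids) {
  keep <- sample_ids(table) %in% ids
  cohort_table(table$data[keep, , drop = FALSE],
               id_column = table$id_column,
               target_column = table$target_column)
}

#' Load a cohort table from CSV or XLSX
#'
#' Reads a rectangular table with a header row. All cells are kept as text;
#' the usual missing-value spellings (empty cell, `NA`, `NaN`, `N/A`,
#' `null`, case-insensitive) are normalized to a single missing marker.
#'
#' @param path file path
#' @param format `"csv"`, `"xlsx"`, or `"auto"` (from the file extension)
#' @return a [cohort_table()]
#' @section Errors: unreadable files, ragged rows and empty tables each raise
#'   a distinct condition class (`cohorteq_unreadable_file`,
#'   `cohorteq_ragged_rows`, `cohorteq_empty_table`).
#' @export
load_table <- function(path, format = c("auto", "csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xlsx", "xls")) "xlsx" else "csv"
  }
  if (!file.exists(path))
    cohorteq_error("cohorteq_unreadable_file",
                   paste0("cannot read file: ", path))
  df <- if (format == "csv") read_csv_cells(path) else read_xlsx_cells(path)
  if (nrow(df) == 0L || ncol(df) == 0L)
    cohorteq_error("cohorteq_empty_table",
                   paste0("table has no data rows: ", path))
  cohort_table(df)
}

read_csv_cells <- function(path) {
  nf <- tryCatch(
    utils::count.fields(path, sep = ",", quote = "\"", blank.lines.skip = TRUE),
    error = function(e)
      cohorteq_error("cohorteq_unreadable_file",
                     paste0("cannot parse file: ", path, " (", conditionMessage(e), ")")))
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0L)
    cohorteq_error("cohorteq_empty_table", paste0("file is empty: ", path))
  if (length(unique(nf)) > 1L)
    cohorteq_error("cohorteq_ragged_rows",
                   sprintf("rows have differing field counts (%s) in %s",
                           paste(unique(nf), collapse = "/"), path))
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    na.strings = character(), strip.white = FALSE),
    error = function(e)
      cohorteq_error("cohorteq_unreadable_file",
                     paste0("cannot parse file: ", path, " (", conditionMessage(e), ")")))
  df
}

#' Write a cohort table to CSV
#'
#' Missing cells are written as empty fields, so a written table re-loads to
#' an identical `cohort_table` (round-trip at cell level).
#'
#' @param table a [cohort_table()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-variable metadata
#'
#' Classifies every column as categorical or continuous and records its
#' role, missingness and distinct-value count. A column is continuous iff
#' all its non-missing cells parse as numbers *and* it has more than
#' `max_categories` distinct values; otherwise it is categorical. Low-
#' cardinality numeric codes (e.g. 0/1 flags) therefore stay categorical,
#' matching how such variables are analysed in baseline tables. Explicit
#' `overrides` win over the inferred kind.
#'
#' @param table a [cohort_table()]
#' @param overrides named character vector or list mapping column name to
#'   `"categorical"` or `"continuous"`
#' @param max_categories discreteness threshold (default 15, the same cap
#'   used for target subpopulations)
#' @return named list of `variable_spec` objects, one per column
#' @export
infer_variable_types <- function(table, overrides = NULL, max_categories = 15L) {
  stopifnot(inherits(table, "cohort_table"))
  overrides <- unlist(overrides)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(table$data))
    if (length(unknown))
      cohorteq_error("cohorteq_unknown_variable",
                     paste0("override names unknown column(s): ",
                            paste(unknown, collapse = ", ")))
    bad <- !overrides %in% c("categorical", "continuous")
    if (any(bad))
      cohorteq_error("cohorteq_bad_override",
                     "overrides must be 'categorical' or 'continuous'")
  }
  specs <- lapply(names(table$data), function(nm) {
    x <- table$data[[nm]]
    obs <- x[!is.na(x)]
    n_distinct <- length(unique(obs))
    numeric_ok <- length(obs) > 0L && !anyNA(parse_number(obs))
    kind <- if (numeric_ok && n_distinct > max_categories) "continuous"
            else "categorical"
    if (nm %in% names(overrides)) kind <- unname(overrides[[nm]])
    role <- if (identical(nm, table$id_column)) "identifier"
            else if (identical(nm, table$target_column)) "target"
            else "feature"
    structure(list(name = nm, kind = kind, role = role,
                   n_missing = sum(is.na(x)),
                   n_distinct = n_distinct,
                   is_binary = n_distinct == 2L),
              class = "variable_spec")
  })
  names(specs) <- names(table$data)
  specs
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s: %s (%s), %d distinct, %d missing%s\n",
              x$name, x$kind, x$role, x$n_distinct, x$n_missing,
              if (x$is_binary) ", binary" else ""))
  invisible(x)
}

#' Assign identifier and target roles
#'
#' Validates that the identifier column is complete and unique and that the
#' target column defines between 2 and 15 subpopulations (the supported
#' cap), then records both roles on the table.
#'
#' @param table a [cohort_table()]
#' @param target name of the target (grouping) column
#' @param identifier name of the unique-identifier column
#' @return the `cohort_table` with roles assigned
#' @export
validate_roles <- function(table, target, identifier) {
  stopifnot(inherits(table, "cohort_table"))
  for (nm in c(target, identifier))
    if (!nm %in% names(table$data))
      cohorteq_error("cohorteq_unknown_variable",
                     paste0("no such column: ", nm))
  if (identical(target, identifier))
    cohorteq_error("cohorteq_role_clash",
                   "target and identifier must be different columns")
  ids <- table$data[[identifier]]
  if (anyNA(ids))
    cohorteq_error("cohorteq_missing_identifier",
                   sprintf("%d sample(s) have a missing identifier", sum(is.na(ids))))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    cohorteq_error("cohorteq_duplicate_identifier",
                   paste0("duplicated identifier value(s): ",
                          paste(utils::head(dup, 5L), collapse = ", ")))
  }
  groups <- unique(table$data[[target]][!is.na(table$data[[target]])])
  if (length(groups) < 2L)
    cohorteq_error("cohorteq_too_few_subpopulations",
                   sprintf("target '%s' has %d subpopulation(s); need at least 2",
                           target, length(groups)))
  if (length(groups) > 15L)
    cohorteq_error("cohorteq_too_many_subpopulations",
                   sprintf("target '%s' has %d subpopulations; the cap is 15",
                           target, length(groups)))
  table$id_column <- identifier
  table$target_column <- target
  table
}

#' Subpopulation sizes of the target variable
#' @param table a [cohort_table()] with roles assigned
#' @return named integer vector of group sizes (names sorted)
#' @export
subpopulation_sizes <- function(table) {
  if (is.null(table$target_column))
    cohorteq_error("cohorteq_no_roles", "target role not assigned yet")
  tg <- table$data[[table$target_column]]
  tab <- table(tg[!is.na(tg)])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}
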