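#' Token-cost estimate for language-model processing of a table
#'
#' Each non-identifier cell is assumed to hold one word, and the guideline
#' of 1000 tokens per 750 words gives 1.333 tokens per word. The estimate
#' is `round_half_up(n_rows * (n_columns - 1) * 1.333)`; the identifier
#' column is excluded from the cell count.
#'
#' @param n_rows number of samples (>= 1)
#' @param n_columns number of columns including the identifier (>= 2)
#' @return estimated token count (integer-valued numeric)
#' @examples
#' estimate_tokens(26, 6)    # 173
#' estimate_tokens(225, 29)  # 8398
#' @export
estimate_tokens <- function(n_rows, n_columns) {
  if (!is.numeric(n_rows) || !is.numeric(n_columns) ||
      n_rows < 1 || n_columns < 2)
    cohorteq_error("cohorteq_bad_dimensions",
                   "need n_rows >= 1 and n_columns >= 2 (identifier plus data)")
  round_half_up(n_rows * (n_columns - 1) * 1.333)
}

# ---- rendering helpers ---------------------------------------------------

# Pipe-aligned plain-text table that parse_rendered_table() can invert.
render_table <- function(df) {
  if (nrow(df) == 0L) return("  (empty)")
  cells <- rbind(names(df), apply(df, 2L, function(col) {
    ifelse(is.na(col), "NA", format(col, trim = TRUE))
  }))
  cells <- matrix(as.character(cells), nrow = nrow(df) + 1L)
  widths <- apply(nchar(cells), 2L, max)
  lines <- apply(cells, 1L, function(row)
    paste(mapply(formatC, row, width = widths, flag = "-"), collapse = " | "))
  paste0("  ", lines)
}

parse_rendered_table <- function(lines) {
  lines <- sub("^  ", "", lines)
  parts <- strsplit(lines, " \\| ")
  header <- trimws(parts[[1]])
  if (length(parts) == 1L) {
    out <- as.data.frame(matrix(character(), ncol = length(header)))
    names(out) <- header
    return(out)
  }
  body <- do.call(rbind, lapply(parts[-1], trimws))
  df <- as.data.frame(body, stringsAsFactors = FALSE)
  names(df) <- header
  for (i in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[i]]))
    if (!anyNA(num[df[[i]] != "NA"])) df[[i]] <- num
  }
  df
}

describe_to_df <- function(desc) {
  if (is.null(desc)) return(NULL)
  if (desc$kind == "categorical") {
    do.call(rbind, lapply(names(desc$groups), function(g) {
      df <- desc$groups[[g]]
      if (nrow(df) == 0L) return(NULL)
      data.frame(group = g, category = df$category, count = df$count,
                 proportion = round(df$proportion, 4),
                 stringsAsFactors = FALSE)
    }))
  } else {
    do.call(rbind, lapply(names(desc$groups), function(g) {
      s <- desc$groups[[g]]
      data.frame(group = g, n = s$n, median = s$median, p25 = s$p25,
                 p75 = s$p75, iqr_width = s$iqr_width,
                 stringsAsFactors = FALSE)
    }))
  }
}

# ---- report --------------------------------------------------------------

#' Build the before/after comparison report
#'
#' Collates dataset structure, missingness, the imputation log, per-variable
#' descriptive summaries with their automated test results before (and,
#' after equalization, after) processing, the impact-score ranking, the
#' category-count percentage-change table, removed/surviving counts, the
#' partition sanity-check verdict and the token estimate. When `result` is
#' `NULL` a statistics-only report (no "after" block) is produced.
#'
#' Percentage change is `100 * (after - before) / before`; a category absent
#' before equalization is reported as 0 change and flagged.
#'
#' @param before the input [cohort_table()] (roles assigned)
#' @param result an `equalize_result`, or `NULL` for a stats-only report
#' @param stats_before named list of per-variable lists with elements
#'   `describe` and `test` (see [run_pipeline()]); computed here if omitted
#' @param stats_after same shape, computed on the kept table; ignored when
#'   `result` is `NULL`
#' @param specs variable specs (recomputed if omitted)
#' @param missingness output of [missingness_summary()] on the raw table
#' @param imputation_log list of `imputation_record`s
#' @param processing_time elapsed seconds to report (optional)
#' @return an object of class `cohort_report`
#' @export
build_report <- function(before, result = NULL, stats_before = NULL,
                         stats_after = NULL, specs = NULL,
                         missingness = NULL, imputation_log = list(),
                         processing_time = NA_real_) {
  stopifnot(inherits(before, "cohort_table"))
  specs <- specs %||% infer_variable_types(before)
  features <- names(which(vapply(specs, function(s) s$role == "feature", logical(1))))
  if (is.null(stats_before))
    stats_before <- lapply(stats::setNames(features, features), function(v)
      list(describe = tryCatch(describe_variable(before, v, specs),
                               error = function(e) NULL),
           test = tryCatch(select_test(before, v, specs), error = function(e) NULL)))
  sanity <- NULL
  pct_change <- NULL
  if (!is.null(result)) {
    sanity <- sanity_check(sample_ids(before), result)
    if (!isTRUE(sanity))
      cohorteq_error("cohorteq_sanity_failure",
                     "sanity check failed; refusing to build a report")
    after_table <- subset_ids(before, result$kept_ids)
    if (is.null(stats_after))
      stats_after <- lapply(stats::setNames(features, features), function(v)
        list(describe = tryCatch(describe_variable(after_table, v, specs),
                                 error = function(e) NULL),
             test = tryCatch(select_test(after_table, v, specs),
                             error = function(e) NULL)))
    pct_change <- percentage_change_table(stats_before, stats_after, specs)
  }
  structure(list(
    n_rows = n_samples(before),
    n_cols = n_variables(before),
    id_column = before$id_column,
    target_column = before$target_column,
    specs = specs,
    sizes_before = subpopulation_sizes(before),
    missingness = missingness %||% missingness_summary(before),
    imputation_log = imputation_log,
    stats_before = stats_before,
    stats_after = stats_after,
    result = result,
    pct_change = pct_change,
    sanity = sanity,
    processing_time = processing_time,
    token_estimate = estimate_tokens(n_samples(before),
                                     max(2L, n_variables(before)))),
    class = "cohort_report")
}

percentage_change_table <- function(stats_before, stats_after, specs) {
  rows <- list()
  for (v in names(stats_before)) {
    if (specs[[v]]$kind != "categorical") next
    db <- describe_to_df(stats_before[[v]]$describe)
    da <- describe_to_df(stats_after[[v]]$describe)
    if (is.null(db)) next
    key_b <- paste(db$group, db$category, sep = "\r")
    key_a <- if (is.null(da)) character() else paste(da$group, da$category, sep = "\r")
    after_counts <- if (is.null(da)) integer() else stats::setNames(da$count, key_a)
    all_keys <- union(key_b, key_a)
    for (k in all_keys) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      b <- if (k %in% key_b) db$count[key_b == k] else 0L
      a <- if (k %in% names(after_counts)) after_counts[[k]] else 0L
      pc <- if (b == 0) 0 else 100 * (a - b) / b
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = parts[1], category = parts[2],
        count_before = b, count_after = a,
        pct_change = round(pc, 2),
        note = if (b == 0) "absent before" else "",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(variable = character(), group = character(),
                  category = character(), count_before = integer(),
                  count_after = integer(), pct_change = numeric(),
                  note = character(), stringsAsFactors = FALSE)
}

#' Render a report to text lines
#'
#' @param x a `cohort_report`
#' @param timestamp include a generation timestamp line (the only
#'   non-deterministic line; disable for byte-identical re-renders)
#' @param ... unused
#' @return character vector of lines
#' @export
format.cohort_report <- function(x, timestamp = TRUE, ...) {
  L <- character()
  add <- function(...) L <<- c(L, ...)
  section <- function(title) add("", paste0("== ", title, " =="))
  add("cohort equalization report")
  if (timestamp) add(paste0("generated: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))

  section("Dataset")
  add(sprintf("  samples: %d", x$n_rows),
      sprintf("  variables: %d", x$n_cols),
      sprintf("  identifier: %s", x$id_column %||% "(unset)"),
      sprintf("  target: %s", x$target_column %||% "(unset)"),
      sprintf("  subpopulations: %s",
              paste(sprintf("%s=%d", names(x$sizes_before), x$sizes_before),
                    collapse = ", ")))

  section("Variable types")
  add(render_table(data.frame(
    variable = names(x$specs),
    kind = vapply(x$specs, `[[`, "", "kind"),
    role = vapply(x$specs, `[[`, "", "role"),
    n_distinct = vapply(x$specs, `[[`, 1L, "n_distinct"),
    n_missing = vapply(x$specs, `[[`, 1L, "n_missing"),
    stringsAsFactors = FALSE)))

  section("Missing values")
  add(render_table(transform(x$missingness,
                             missing_fraction = round(missing_fraction, 4))))

  section("Imputation log")
  if (length(x$imputation_log)) {
    add(render_table(data.frame(
      variable = vapply(x$imputation_log, `[[`, "", "variable"),
      method = vapply(x$imputation_log, `[[`, "", "method"),
      n_imputed = vapply(x$imputation_log, `[[`, 1L, "n_imputed"),
      fill_value = vapply(x$imputation_log, function(r)
        format(r$fill_value, digits = 6), character(1)),
      stringsAsFactors = FALSE)))
  } else add("  (no imputation performed)")

  stats_block <- function(stats, label) {
    section(paste0("Statistics (", label, ")"))
    tests <- data.frame(variable = character(), test = character(),
                        statistic = numeric(), p_value = character(),
                        normality_p = character(), stringsAsFactors = FALSE)
    for (v in names(stats)) {
      tst <- stats[[v]]$test
      if (!is.null(tst))
        tests <- rbind(tests, data.frame(
          variable = v, test = tst$test_name,
          statistic = round(tst$statistic, 4),
          p_value = format_p(tst$p_value),
          normality_p = if (is.na(tst$normality_p)) "-" else format_p(tst$normality_p),
          stringsAsFactors = FALSE))
    }
    add(render_table(tests))
    for (v in names(stats)) {
      desc <- stats[[v]]$describe
      df <- describe_to_df(desc)
      if (is.null(df)) next
      add("", paste0("  -- ", v, " (", desc$kind, ") --"))
      add(render_table(df))
    }
  }
  stats_block(x$stats_before, "before")

  if (!is.null(x$result)) {
    res <- x$result
    section("Equalization")
    add(sprintf("  method: %s (bypass=%s, seed=%d, min_threshold=%d)",
                res$config$method, res$config$bypass, res$config$seed,
                res$config$min_threshold),
        sprintf("  surviving samples: %d", length(res$kept_ids)),
        sprintf("  removed samples: %d", length(res$removed_ids)),
        sprintf("  target size: %d", res$target_size),
        sprintf("  iterations: %d", res$iterations_run),
        sprintf("  sizes after: %s",
                paste(sprintf("%s=%d", names(res$sizes_after), res$sizes_after),
                      collapse = ", ")))
    for (fl in res$flags) add(paste0("  note: ", fl))

    section("Impact-score ranking")
    if (length(res$impact_scores))
      add(render_table(data.frame(variable = names(res$impact_scores),
                                  impact = round(res$impact_scores, 4),
                                  stringsAsFactors = FALSE)))
    else add("  (no variables configured)")

    stats_block(x$stats_after, "after")

    section("Percentage changes")
    add(render_table(x$pct_change))

    section("Sanity check")
    add(sprintf("  kept and removed samples partition the input: %s",
                if (isTRUE(x$sanity)) "PASS" else "FAIL"))
  }

  section("Resources")
  if (!is.na(x$processing_time))
    add(sprintf("  processing time (s): %.2f", x$processing_time))
  add(sprintf("  estimated tokens (1.333 per non-identifier cell): %d",
              as.integer(x$token_estimate)))
  L
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(format(x, timestamp = FALSE), sep = "\n")
  invisible(x)
}

#' Save a report as a formatted text file
#'
#' @param report a `cohort_report`
#' @param path output path (`.txt`); the directory must exist
#' @param timestamp include the generation timestamp line
#' @return `path`, invisibly
#' @export
save_report <- function(report, path, timestamp = TRUE) {
  stopifnot(inherits(report, "cohort_report"))
  if (!dir.exists(dirname(path)))
    cohorteq_error("cohorteq_unwritable_path",
                   paste0("directory does not exist: ", dirname(path)))
  writeLines(format(report, timestamp = timestamp), path, useBytes = TRUE)
  invisible(path)
}

#' Parse the numeric tables back out of a saved report
#'
#' Reads a report written by [save_report()] and re-parses each pipe-aligned
#' table under its section heading.
#'
#' @param path path to the saved `.txt` report
#' @return named list of data.frames, one per section containing a table
#'   (sections with repeated tables get `section: subtitle` names)
#' @export
parse_report_tables <- function(path) {
  lines <- readLines(path)
  out <- list()
  current <- NULL
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^== .* ==$", ln)) {
      current <- sub("^== (.*) ==$", "\\1", ln)
    } else if (grepl("^  -- .* --$", ln)) {
      current <- paste0(current, ": ", sub("^  -- (.*) --$", "\\1", ln))
    } else if (grepl(" \\| ", ln)) {
      j <- i
      while (j < length(lines) && grepl(" \\| ", lines[j + 1L])) j <- j + 1L
      nm <- current %||% "table"
      if (nm %in% names(out)) nm <- paste0(nm, " (", sum(names(out) == nm) + 1L, ")")
      out[[nm]] <- parse_rendered_table(lines[i:j])
      i <- j
    }
    i <- i + 1L
  }
  out
}

#' Full analysis pipeline
#'
#' Loads no files itself: takes a role-assigned [cohort_table()], imputes
#' missing values, computes before statistics for every feature, optionally
#' equalizes, recomputes statistics on the surviving samples, and builds
#' the report.
#'
#' @param table a [cohort_table()] with roles assigned
#' @param config an [equalize_config()], or `NULL` for statistics only
#' @param overrides type-inference overrides passed to
#'   [infer_variable_types()]
#' @param impute impute missing values first (default `TRUE`)
#' @return list with `table` (imputed), `result` (`NULL` in stats mode),
#'   `report`, `specs`, `imputation_log`
#' @export
run_pipeline <- function(table, config = NULL, overrides = NULL, impute = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  missingness <- missingness_summary(table)
  specs <- infer_variable_types(table, overrides = overrides)
  log <- list()
  if (impute) {
    imp <- impute_cohort(table, specs)
    table <- imp$table
    log <- imp$log
    specs <- infer_variable_types(table, overrides = overrides)
  }
  result <- if (!is.null(config)) equalize(table, config)
  report <- build_report(table, result = result, specs = specs,
                         missingness = missingness, imputation_log = log,
                         processing_time = proc.time()[["elapsed"]] - t0)
  list(table = table, result = result, report = report, specs = specs,
       imputation_log = log)
}
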