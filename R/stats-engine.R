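#' Automated statistical testing
#'
#' The engine mirrors the standard decision tree for baseline-characteristic
#' tables. Categorical features are cross-tabulated against the target and
#' tested with the chi-square test (Yates continuity correction for 2x2
#' tables); when a 2x2 table has any expected cell count below 5, Fisher's
#' exact test is used instead. Continuous features are gated by a
#' Shapiro-Wilk normality check (normal iff p > 0.05): two groups get a
#' Welch t-test (normal) or Mann-Whitney U (non-normal); three or more
#' groups get one-way ANOVA with Tukey's HSD (normal) or Kruskal-Wallis
#' with Dunn's Bonferroni-adjusted post hoc (non-normal).
#'
#' @name stats_engine
NULL

new_test_result <- function(variable, test_name, statistic, p_value,
                            normality_p = NA_real_, posthoc = NULL,
                            warning = NA_character_) {
  structure(list(variable = variable, test_name = test_name,
                 statistic = unname(statistic), p_value = unname(p_value),
                 normality_p = normality_p, posthoc = posthoc,
                 warning = warning),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: %s, statistic=%.4g, p=%s\n",
              x$variable, x$test_name, x$statistic, format_p(x$p_value)))
  if (!is.null(x$posthoc) && nrow(x$posthoc))
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("  post hoc %s: p=%s\n", x$posthoc$pair[i],
                  format_p(x$posthoc$p_value[i])))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric sample, n between 3 and 5000 (larger samples are
#'   thinned deterministically to 5000 evenly spaced order statistics, which
#'   preserves the empirical distribution shape)
#' @return list with `W` and `p`; a sample is treated as normal iff
#'   `p > 0.05`
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L)
    cohorteq_error("cohorteq_too_few_values",
                   "Shapiro-Wilk needs at least 3 non-missing values")
  if (stats::sd(values) == 0)
    cohorteq_error("cohorteq_constant_sample",
                   "Shapiro-Wilk is undefined for a constant sample")
  if (length(values) > 5000L) {
    idx <- round(seq(1L, length(values), length.out = 5000L))
    values <- sort(values)[idx]
  }
  res <- stats::shapiro.test(values)
  list(W = unname(res$statistic), p = unname(res$p.value))
}

as_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    cohorteq_error("cohorteq_bad_contingency",
                   "contingency counts must be non-negative integers")
  if (sum(counts) == 0)
    cohorteq_error("cohorteq_bad_contingency", "contingency table is empty")
  counts
}

expected_counts <- function(counts) {
  outer(rowSums(counts), colSums(counts)) / sum(counts)
}

#' Chi-square test of independence
#'
#' 2x2 tables use the Yates continuity correction; larger tables use the
#' uncorrected Pearson statistic. The p-value comes from the chi-square
#' distribution with (r-1)(c-1) degrees of freedom.
#'
#' @param counts contingency matrix (feature categories x subpopulations)
#' @param variable variable name carried into the result
#' @return a `test_result`
#' @export
chi_square_test <- function(counts, variable = "variable") {
  counts <- as_contingency(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    cohorteq_error("cohorteq_zero_margin",
                   "contingency table has an empty row or column")
  is2x2 <- all(dim(counts) == c(2L, 2L))
  res <- suppressWarnings(stats::chisq.test(counts, correct = is2x2))
  warn <- if (!is2x2 && any(expected_counts(counts) < 5))
    "expected cell count < 5 in an r x c table; chi-square may be unreliable"
  else NA_character_
  new_test_result(variable,
                  if (is2x2) "chi_square" else "chi_square",
                  res$statistic, res$p.value, warning = warn)
}

#' Fisher's exact test for 2x2 tables
#'
#' Two-sided p-value: the sum of hypergeometric probabilities, at fixed
#' margins, of every table at most as probable as the observed one.
#'
#' @inheritParams chi_square_test
#' @return a `test_result`
#' @export
fisher_exact <- function(counts, variable = "variable") {
  counts <- as_contingency(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    cohorteq_error("cohorteq_bad_contingency",
                   "Fisher's exact test expects a 2x2 table")
  res <- stats::fisher.test(counts)
  new_test_result(variable, "fisher_exact", NA_real_, res$p.value)
}

#' Welch two-sample t-test
#'
#' @param a,b numeric samples for the two subpopulations
#' @param variable variable name carried into the result
#' @return a `test_result` (two-sided p)
#' @export
t_test_independent <- function(a, b, variable = "variable") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    cohorteq_error("cohorteq_too_few_values", "t-test needs n >= 2 per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && isTRUE(all.equal(mean(a), mean(b))))
    return(new_test_result(variable, "t_test", 0, 1))
  if (stats::sd(c(a, b)) == 0)
    cohorteq_error("cohorteq_constant_sample", "t-test undefined for constant data")
  res <- stats::t.test(a, b, var.equal = FALSE)
  new_test_result(variable, "t_test", res$statistic, res$p.value)
}

#' Mann-Whitney U test
#'
#' Exact two-sided p from the null rank distribution when the smaller group
#' has at most 8 observations and there are no ties; otherwise a normal
#' approximation with continuity and tie correction.
#'
#' @inheritParams t_test_independent
#' @return a `test_result`; the statistic is U for the first sample
#' @export
mann_whitney_u <- function(a, b, variable = "variable") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    cohorteq_error("cohorteq_too_few_values",
                   "Mann-Whitney needs non-empty samples")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= 8L
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  new_test_result(variable, "mann_whitney_u", res$statistic, res$p.value)
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' @param groups named list of numeric samples, one per subpopulation
#'   (at least 3 groups, each with n >= 2)
#' @param variable variable name carried into the result
#' @return a `test_result` whose `posthoc` holds Tukey pairwise p-values
#' @export
anova_oneway <- function(groups, variable = "variable") {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 3L)
    cohorteq_error("cohorteq_too_few_groups", "ANOVA here expects >= 3 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    cohorteq_error("cohorteq_too_few_values", "every group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups) %||% seq_along(groups),
                       vapply(groups, length, integer(1))))
  if (stats::sd(values) == 0)
    return(new_test_result(variable, "anova", 0, 1,
                           posthoc = data.frame(pair = character(),
                                                p_value = numeric())))
  fit <- stats::aov(values ~ labels)
  tab <- summary(fit)[[1]]
  tukey <- stats::TukeyHSD(fit)$labels
  posthoc <- data.frame(pair = rownames(tukey), p_value = tukey[, "p adj"],
                        stringsAsFactors = FALSE)
  rownames(posthoc) <- NULL
  new_test_result(variable, "anova", tab[["F value"]][1], tab[["Pr(>F)"]][1],
                  posthoc = posthoc)
}

#' Kruskal-Wallis test with Dunn's post hoc
#'
#' H statistic with tie correction and chi-square p-value; pairwise Dunn
#' z-tests on mean ranks, Bonferroni-adjusted, are appended. When every
#' observation is identical the statistic is reported as 0 with p = 1.
#'
#' @inheritParams anova_oneway
#' @return a `test_result` whose `posthoc` holds Dunn pairwise p-values
#' @export
kruskal_wallis <- function(groups, variable = "variable") {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 3L)
    cohorteq_error("cohorteq_too_few_groups",
                   "Kruskal-Wallis here expects >= 3 groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    cohorteq_error("cohorteq_too_few_values", "every group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups) %||% seq_along(groups),
                       vapply(groups, length, integer(1))))
  if (length(unique(values)) == 1L)
    return(new_test_result(variable, "kruskal_wallis", 0, 1,
                           posthoc = data.frame(pair = character(),
                                                p_value = numeric())))
  res <- stats::kruskal.test(values, labels)
  posthoc <- dunn_posthoc(values, labels)
  new_test_result(variable, "kruskal_wallis", res$statistic, res$p.value,
                  posthoc = posthoc)
}

#' Dunn's pairwise rank-sum comparisons
#'
#' Standard Dunn z statistics on mean ranks of the pooled sample, with the
#' usual tie correction, two-sided p-values and Bonferroni adjustment.
#'
#' @param values pooled numeric observations
#' @param labels factor of group labels, same length as `values`
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#' @return data.frame with `pair`, `z`, `p_raw`, `p_value` (adjusted)
#' @export
dunn_posthoc <- function(values, labels, adjust = "bonferroni") {
  labels <- droplevels(as.factor(labels))
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, labels, mean)
  sizes <- tapply(r, labels, length)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  lv <- levels(labels)
  pairs <- utils::combn(lv, 2L)
  out <- apply(pairs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
             z = out["z", ],
             p_raw = out["p", ],
             p_value = stats::p.adjust(out["p", ], method = adjust),
             stringsAsFactors = FALSE)
}

#' Build the feature-by-target contingency table
#'
#' Rows are feature categories, columns are target subpopulations; rows
#' with a missing feature or target value are dropped.
#'
#' @param table a [cohort_table()] with roles assigned
#' @param variable feature column name
#' @return integer matrix of counts
#' @export
contingency_table <- function(table, variable) {
  x <- table$data[[variable]]
  g <- table$data[[table$target_column]]
  keep <- !is.na(x) & !is.na(g)
  tab <- table(x[keep], g[keep])
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Automated test selection for one feature variable
#'
#' Applies the decision tree described in [stats_engine]: contingency-based
#' tests for categorical features (Fisher fallback when a 2x2 table has any
#' expected count below 5), normality-gated location tests for continuous
#' features.
#'
#' @param table a [cohort_table()] with roles assigned
#' @param variable feature column name
#' @param specs variable specs (recomputed if omitted)
#' @param alpha significance level used only for the normality gate display
#' @return a `test_result`
#' @export
select_test <- function(table, variable, specs = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "cohort_table"))
  specs <- specs %||% infer_variable_types(table)
  spec <- specs[[variable]]
  if (is.null(spec))
    cohorteq_error("cohorteq_unknown_variable", paste0("no such column: ", variable))
  g <- table$data[[table$target_column]]
  n_groups <- length(unique(g[!is.na(g)]))
  if (n_groups < 2L)
    cohorteq_error("cohorteq_too_few_subpopulations",
                   "need at least 2 subpopulations to compare")
  if (spec$kind == "categorical") {
    counts <- contingency_table(table, variable)
    if (nrow(counts) < 2L)
      cohorteq_error("cohorteq_constant_feature",
                     paste0("feature '", variable, "' is constant; nothing to test"))
    exp_counts <- expected_counts(counts)
    if (all(dim(counts) == c(2L, 2L)) && any(exp_counts < 5))
      fisher_exact(counts, variable)
    else
      chi_square_test(counts, variable)
  } else {
    x <- parse_number(table$data[[variable]])
    keep <- !is.na(x) & !is.na(g)
    x <- x[keep]; g <- factor(g[keep])
    if (length(unique(x)) == 1L)
      cohorteq_error("cohorteq_constant_feature",
                     paste0("feature '", variable, "' is constant; nothing to test"))
    sw <- shapiro_wilk(x)
    normal <- sw$p > 0.05
    groups <- split(x, g)
    res <- if (n_groups == 2L) {
      if (normal) t_test_independent(groups[[1]], groups[[2]], variable)
      else mann_whitney_u(groups[[1]], groups[[2]], variable)
    } else {
      if (normal) anova_oneway(groups, variable)
      else kruskal_wallis(groups, variable)
    }
    res$normality_p <- sw$p
    res
  }
}

#' Per-group descriptive summary
#'
#' Categorical variables: per-group counts and proportions (proportions are
#' exact; a display copy is rounded to 2 decimals). Continuous variables:
#' per-group median, 25th and 75th percentiles (linear interpolation) and
#' the IQR width p75 - p25.
#'
#' @param table a [cohort_table()] with roles assigned
#' @param variable feature or target column name
#' @param specs variable specs (recomputed if omitted)
#' @return a `descriptive_summary`: list with `variable`, `kind`, and
#'   `groups` (named list of per-group data.frames / stat lists)
#' @export
describe_variable <- function(table, variable, specs = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  specs <- specs %||% infer_variable_types(table)
  spec <- specs[[variable]]
  if (is.null(spec))
    cohorteq_error("cohorteq_unknown_variable", paste0("no such column: ", variable))
  g <- table$data[[table$target_column]]
  x <- table$data[[variable]]
  keep <- !is.na(g)
  groups <- split(x[keep], g[keep])
  out <- if (spec$kind == "categorical") {
    lapply(groups, function(v) {
      v <- v[!is.na(v)]
      tab <- table(v)
      df <- data.frame(category = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
      df$proportion <- if (nrow(df)) df$count / sum(df$count) else numeric()
      df$proportion_display <- round(df$proportion, 2)
      df
    })
  } else {
    lapply(groups, function(v) {
      v <- parse_number(v)
      v <- v[!is.na(v)]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      list(n = length(v), median = q[2], p25 = q[1], p75 = q[3],
           iqr_width = q[3] - q[1])
    })
  }
  structure(list(variable = variable, kind = spec$kind, groups = out),
            class = "descriptive_summary")
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat(sprintf("<descriptive_summary> %s (%s)\n", x$variable, x$kind))
  for (g in names(x$groups)) {
    if (x$kind == "categorical") {
      df <- x$groups[[g]]
      cat(sprintf("  %s: %s\n", g,
                  paste(sprintf("%s %d (%.2f)", df$category, df$count,
                                df$proportion), collapse = ", ")))
    } else {
      s <- x$groups[[g]]
      cat(sprintf("  %s: median %.4g (IQR %.4g; %.4g-%.4g), n=%d\n",
                  g, s$median, s$iqr_width, s$p25, s$p75, s$n))
    }
  }
  invisible(x)
}
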