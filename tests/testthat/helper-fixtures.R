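# Shared fixture builders. Everything is generated in code; nothing binary
# ships with the package.

# A tiny table built directly from vectors; roles assigned when both names
# are given.
make_table <- function(..., .id = NULL, .target = NULL) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  tab <- cohort_table(df)
  if (!is.null(.id) && !is.null(.target))
    tab <- validate_roles(tab, target = .target, identifier = .id)
  tab
}

# A table with the given subpopulation sizes and an optional per-group
# category probability for one binary feature.
make_group_table <- function(sizes, prevalence = NULL, seed = 1) {
  n <- sum(sizes)
  df <- data.frame(id = sprintf("X%04d", seq_len(n)),
                   grp = rep(names(sizes), times = sizes),
                   stringsAsFactors = FALSE)
  if (!is.null(prevalence)) {
    set.seed(seed)
    df$flag <- unlist(lapply(names(sizes), function(g)
      ifelse(stats::runif(sizes[[g]]) < prevalence[[g]], "yes", "no")))
  }
  validate_roles(cohort_table(df), target = "grp", identifier = "id")
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Exact two-sided Fisher p by full hypergeometric enumeration (independent
# of stats::fisher.test): sum the probabilities of all tables with the
# observed margins whose point probability is at most the observed one.
fisher_enumeration_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  n <- r1 + r2
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a)
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1), numeric(1))
  p_obs <- probs[a_range == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of ranks
# to the first sample (no ties assumed).
mwu_enumeration_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combos <- utils::combn(na + nb, na)
  ranks <- seq_len(na + nb)
  u_all <- apply(combos, 2, function(idx) sum(ranks[idx]) - na * (na + 1) / 2)
  lower <- mean(u_all <= u_obs)
  upper <- mean(u_all >= u_obs)
  min(1, 2 * min(lower, upper))
}

# Empirical prevalence of a binary category within one subpopulation.
group_prevalence <- function(table, variable, group, category = "yes") {
  x <- table$data[[variable]][table$data[[table$target_column]] == group]
  x <- x[!is.na(x)]
  mean(x == category)
}

confounder_gap <- function(table) {
  abs(group_prevalence(table, "exposure", "case") -
        group_prevalence(table, "exposure", "control"))
}
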