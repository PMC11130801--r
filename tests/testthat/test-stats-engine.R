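test_that("Shapiro-Wilk gate classifies shape and rejects degenerate input", {
  expect_error(shapiro_wilk(c(2, 2, 2, 2)), class = "cohorteq_constant_sample")
  expect_error(shapiro_wilk(c(1, 2)), class = "cohorteq_too_few_values")
  set.seed(11)
  bell <- rnorm(100)
  expo <- rexp(100)
  expect_gt(shapiro_wilk(bell)$p, 0.05)
  expect_lt(shapiro_wilk(expo)$p, 0.05)
  expect_true(shapiro_wilk(bell)$W > 0 && shapiro_wilk(bell)$W <= 1)
})

test_that("chi-square applies Yates correction to 2x2 tables", {
  # balanced table: observed equals expected
  even <- chi_square_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  # every |O - E| < 0.5: corrected statistic collapses to 0
  tiny_dev <- chi_square_test(matrix(c(44, 68, 40, 63), 2))
  expect_equal(tiny_dev$p_value, 1)

  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)),
               class = "cohorteq_zero_margin")

  # 3x2 tables use the uncorrected Pearson statistic
  m <- matrix(c(20, 30, 10, 25, 28, 12), ncol = 2)
  res <- chi_square_test(m)
  expect_equal(res$statistic,
               unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic))
})

test_that("Fisher exact p equals hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  m <- matrix(c(8, 1, 2, 9), 2)
  expect_equal(fisher_exact(m)$p_value, fisher_enumeration_p(m),
               tolerance = 1e-10)
  expect_error(fisher_exact(matrix(1:6, 2)), class = "cohorteq_bad_contingency")
})

test_that("Fisher exact matches the enumeration oracle on all small tables", {
  for (r1 in 1:8) for (r2 in 1:8) for (c1 in 1:(r1 + r2 - 1)) {
    a <- max(0, c1 - r2)
    m <- matrix(c(a, c1 - a, r1 - a, r2 - (c1 - a)), 2)
    if (any(m < 0) || any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(m)$p_value, fisher_enumeration_p(m),
                 tolerance = 1e-9)
  }
})

test_that("t-test is two-sided, symmetric, and exact on a closed-form case", {
  same <- t_test_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- c(1, 2, 3); b <- a + 10
  res <- t_test_independent(a, b)
  # closed form: equal variances so Welch reduces to the pooled t with 4 df
  t_expected <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(res$statistic, t_expected)
  expect_equal(res$p_value, 2 * pt(-abs(t_expected), df = 4))
  expect_lt(res$p_value, 0.01)

  swapped <- t_test_independent(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)
})

test_that("Mann-Whitney U uses the exact null for small untied samples", {
  tied <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(tied$p_value, 1)

  # complete separation at n = 5 per group: 2 / choose(10, 5)
  sep <- mann_whitney_u(1:5, 6:10)
  expect_equal(sep$p_value, 2 / 252)

  a <- c(1.2, 3.4, 2.2); b <- c(0.5, 4.1, 5.3, 2.9)
  expect_equal(mann_whitney_u(a, b)$p_value, mann_whitney_u(b, a)$p_value)
})

test_that("exact Mann-Whitney p equals rank-arrangement enumeration", {
  set.seed(23)
  for (rep in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    vals <- sample(seq_len(50), na + nb)   # distinct -> no ties
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(mann_whitney_u(a, b)$p_value, mwu_enumeration_p(a, b),
                 tolerance = 1e-9)
  }
})

test_that("one-way ANOVA and Tukey isolate a shifted group", {
  idg <- list(g1 = c(1, 2, 3), g2 = c(1, 2, 3), g3 = c(1, 2, 3))
  same <- anova_oneway(idg)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  groups <- list(a = c(5.1, 4.9, 5.0, 5.2),
                 b = c(5.0, 5.1, 4.8, 5.1),
                 c = c(9.0, 9.2, 8.9, 9.1))
  res <- anova_oneway(groups)
  # closed-form F on the fixture
  k <- 3; n <- 12
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  f_expected <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$statistic, f_expected, tolerance = 1e-9)
  expect_lt(res$p_value, 0.01)
  ph <- res$posthoc
  expect_lt(ph$p_value[ph$pair == "c-a"], 0.05)
  expect_lt(ph$p_value[ph$pair == "c-b"], 0.05)
  expect_gt(ph$p_value[ph$pair == "b-a"], 0.05)

  perm <- anova_oneway(groups[c(3, 1, 2)])
  expect_equal(perm$statistic, res$statistic)

  expect_error(anova_oneway(list(a = 1, b = c(1, 2), c = c(3, 4))),
               class = "cohorteq_too_few_values")
})

test_that("Kruskal-Wallis H matches brute-force ranks; Dunn is adjusted", {
  flat <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  groups <- list(a = c(1, 4, 7), b = c(2, 5, 9), c = c(3, 6, 8))
  res <- kruskal_wallis(groups)
  # untied fixture: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2
  vals <- unlist(groups); N <- length(vals); r <- rank(vals)
  rg <- tapply(r, rep(names(groups), lengths(groups)), mean)
  h_expected <- 12 / (N * (N + 1)) * sum(3 * (rg - (N + 1) / 2)^2)
  expect_equal(res$statistic, h_expected, tolerance = 1e-9)

  shifted <- kruskal_wallis(list(a = 1:6, b = 2:7, c = 101:106))
  expect_true(all(shifted$posthoc$p_value >= shifted$posthoc$p_raw))
  expect_true(all(shifted$posthoc$p_value <= 1))
})

test_that("test selection follows the decision tree", {
  # 2 groups, binary feature, all expected counts >= 5 -> chi-square
  tab <- make_group_table(c(A = 60, B = 60), prevalence = c(A = 0.5, B = 0.5))
  expect_equal(select_test(tab, "flag")$test_name, "chi_square")

  # 2x2 with all expected counts below 5 -> Fisher
  small <- make_table(id = as.character(1:10),
                      g = rep(c("A", "B"), each = 5),
                      v = c("x", "x", "y", "y", "y", "x", "x", "x", "y", "y"),
                      .id = "id", .target = "g")
  exp_counts <- outer(rowSums(contingency_table(small, "v")),
                      colSums(contingency_table(small, "v"))) / 10
  expect_true(any(exp_counts < 5))
  expect_equal(select_test(small, "v")$test_name, "fisher_exact")

  # continuous, non-normal, 2 groups -> Mann-Whitney
  set.seed(3)
  skew <- make_table(id = as.character(1:120),
                     g = rep(c("A", "B"), each = 60),
                     v = as.character(round(rexp(120), 4)),
                     .id = "id", .target = "g")
  res <- select_test(skew, "v", specs = infer_variable_types(
    skew, overrides = c(v = "continuous")))
  expect_equal(res$test_name, "mann_whitney_u")
  expect_lt(res$normality_p, 0.05)

  # continuous, normal, 3 groups -> ANOVA (and non-normal -> Kruskal-Wallis)
  set.seed(4)
  tri <- make_table(id = as.character(1:150),
                    g = rep(c("A", "B", "C"), each = 50),
                    v = as.character(round(rnorm(150, 50, 5), 4)),
                    .id = "id", .target = "g")
  sp <- infer_variable_types(tri, overrides = c(v = "continuous"))
  expect_equal(select_test(tri, "v", specs = sp)$test_name, "anova")
  tri$data$v <- as.character(round(rexp(150), 4))
  sp <- infer_variable_types(tri, overrides = c(v = "continuous"))
  expect_equal(select_test(tri, "v", specs = sp)$test_name, "kruskal_wallis")

  # constant feature cannot be tested
  const <- make_table(id = as.character(1:6), g = rep(c("A", "B"), 3),
                      v = rep("same", 6), .id = "id", .target = "g")
  expect_error(select_test(const, "v"), class = "cohorteq_constant_feature")
})

test_that("chi-square and Fisher agree asymptotically on well-filled tables", {
  # mid-p discrepancies shrink as cell counts grow; at expected counts in
  # the hundreds the two tests track each other within 0.05 absolute
  set.seed(31)
  for (rep in 1:25) {
    m <- matrix(rpois(4, lambda = 400) + 100, 2)
    expect_true(all(outer(rowSums(m), colSums(m)) / sum(m) >= 20))
    p_chi <- chi_square_test(m)$p_value
    p_fis <- fisher_exact(m)$p_value
    expect_lt(abs(p_chi - p_fis), 0.05)
    expect_true(p_chi >= 0 && p_chi <= 1 && p_fis >= 0 && p_fis <= 1)
  }
})

test_that("descriptive summaries report counts/proportions and IQR", {
  tab <- make_table(id = as.character(1:8),
                    g = rep(c("A", "B"), each = 4),
                    v = c("f", "f", "m", "m", "f", "m", "m", "m"),
                    .id = "id", .target = "g")
  d <- describe_variable(tab, "v")
  expect_equal(d$kind, "categorical")
  for (g in names(d$groups))
    expect_equal(sum(d$groups[[g]]$proportion), 1, tolerance = 1e-9)

  # a group of 112 with 44 in one category displays as 0.39
  expect_equal(round(44 / 112, 2), 0.39)

  cont <- make_table(id = as.character(1:10),
                     g = rep(c("A", "B"), each = 5),
                     v = as.character(c(1:5, 11:15)),
                     .id = "id", .target = "g")
  sp <- infer_variable_types(cont, overrides = c(v = "continuous"))
  dc <- describe_variable(cont, "v", specs = sp)
  expect_equal(dc$groups$A$median, 3)
  expect_equal(dc$groups$A$p25, 2)
  expect_equal(dc$groups$A$p75, 4)
  expect_equal(dc$groups$A$iqr_width, 2)

  single <- make_table(id = as.character(1:4), g = rep(c("A", "B"), 2),
                       v = rep("only", 4), .id = "id", .target = "g")
  ds <- describe_variable(single, "v")
  expect_equal(ds$groups$A$proportion, 1)
})
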