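test_that("impact scores measure total-variation deviation from pooled", {
  # identical distributions in both groups -> 0
  tab <- make_table(id = as.character(1:8), g = rep(c("A", "B"), each = 4),
                    v = rep(c("x", "x", "y", "y"), 2),
                    .id = "id", .target = "g")
  expect_equal(unname(compute_impact_scores(tab, "v")), 0)

  # perfect separation of two equal groups -> 0.5 + 0.5 = 1
  sep <- make_table(id = as.character(1:8), g = rep(c("A", "B"), each = 4),
                    v = rep(c("a", "b"), each = 4),
                    .id = "id", .target = "g")
  expect_equal(unname(compute_impact_scores(sep, "v")), 1)

  # random 2-group 3-category fixture vs direct arithmetic
  set.seed(19)
  g <- rep(c("A", "B"), times = c(40, 25))
  v <- sample(c("r", "s", "t"), 65, replace = TRUE)
  tab3 <- make_table(id = as.character(1:65), g = g, v = v,
                     .id = "id", .target = "g")
  pool <- prop.table(table(v))
  oracle <- sum(vapply(c("A", "B"), function(gr) {
    pg <- prop.table(table(factor(v[g == gr], levels = names(pool))))
    0.5 * sum(abs(pg - pool))
  }, numeric(1)))
  expect_equal(unname(compute_impact_scores(tab3, "v")), oracle,
               tolerance = 1e-12)

  expect_error(compute_impact_scores(tab3, "nope"),
               class = "cohorteq_unknown_variable")
})

test_that("equalize_samples downsamples every group to the smallest", {
  tab <- make_group_table(c(A = 10, B = 6, C = 8))
  res <- equalize_samples(tab, equalize_config("samples", seed = 2))
  expect_equal(unname(res$sizes_after), c(6L, 6L, 6L))
  expect_equal(length(res$removed_ids), 6L)
  expect_true(sanity_check(sample_ids(tab), res))

  eq <- make_group_table(c(A = 5, B = 5))
  res_eq <- equalize_samples(eq, equalize_config("samples", seed = 2))
  expect_equal(length(res_eq$removed_ids), 0L)
})

test_that("protected samples survive even at the cost of equal sizes", {
  tab <- make_group_table(c(A = 10, B = 6))
  prot <- sample_ids(tab)[1:8]  # 8 protected ids, all in A
  res <- equalize_samples(tab, equalize_config("samples", seed = 1,
                                               protected_ids = prot))
  expect_equal(res$sizes_after[["A"]], 8L)
  expect_true(all(prot %in% res$kept_ids))
  expect_true(length(res$flags) > 0)
  expect_error(
    equalize_samples(tab, equalize_config("samples", protected_ids = "ghost")),
    class = "cohorteq_unknown_identifier")
})

test_that("proportion equalization removes nothing from a balanced cohort", {
  tab <- make_table(id = as.character(1:40),
                    g = rep(c("A", "B"), each = 20),
                    v = rep(rep(c("x", "y"), each = 10), 2),
                    .id = "id", .target = "g")
  res <- equalize_proportions(tab, equalize_config("proportions",
                                                   variables = "v", seed = 1))
  expect_equal(length(res$removed_ids), 0L)
  expect_equal(res$iterations_run, 0L)
})

test_that("proportion equalization balances a confounder (bypass mode)", {
  tab <- standard_confounded_fixture(11)
  tab <- impute_cohort(tab)$table
  cfg <- equalize_config("proportions", variables = "exposure",
                         bypass = TRUE, seed = 2)
  res <- equalize_proportions(tab, cfg)
  kept <- subset_ids(tab, res$kept_ids)
  expect_lt(confounder_gap(kept), 0.1)
  expect_gt(select_test(kept, "exposure")$p_value, 0.05)
  expect_lt(res$impact_final, sum(res$impact_scores))
  expect_true(sanity_check(sample_ids(tab), res))
})

test_that("without bypass the smallest subpopulation is never touched", {
  tab <- standard_confounded_fixture(13)
  cfg <- equalize_config("proportions", variables = "exposure",
                         bypass = FALSE, seed = 3)
  res <- equalize_proportions(tab, cfg)
  control_ids <- sample_ids(tab)[tab$data$group == "control"]
  expect_length(intersect(res$removed_ids, control_ids), 0)
})

test_that("advanced equalization reduces to size equalization when balanced", {
  tab <- make_table(id = sprintf("i%03d", 1:50),
                    g = rep(c("A", "B"), times = c(30, 20)),
                    v = rep(c("x", "y"), 25),
                    .id = "id", .target = "g")
  cfg <- equalize_config("advanced", variables = "v",
                         min_threshold = 20, seed = 1)
  res <- advanced_equalize(tab, cfg)
  expect_equal(unname(res$sizes_after), c(20L, 20L))
  expect_true(sanity_check(sample_ids(tab), res))
})

test_that("advanced equalization honors MinThreshold and protection", {
  tab <- standard_confounded_fixture(21)
  prot <- sample_ids(tab)[tab$data$group == "case"][1:10]
  cfg <- equalize_config("advanced", variables = c("exposure", "sex", "age"),
                         min_threshold = 40, seed = 5, protected_ids = prot)
  res <- advanced_equalize(tab, cfg)
  expect_true(all(res$sizes_after >= 40))
  expect_length(intersect(res$removed_ids, prot), 0)
  expect_lt(res$impact_final, sum(res$impact_scores))
  expect_true(sanity_check(sample_ids(tab), res))

  expect_error(
    advanced_equalize(tab, equalize_config("advanced", variables = "exposure",
                                           min_threshold = 101)),
    class = "cohorteq_bad_threshold")
})

test_that("equalization is deterministic for a fixed seed", {
  tab <- standard_confounded_fixture(2)
  cfg <- equalize_config("advanced", variables = c("exposure", "age"), seed = 9)
  r1 <- advanced_equalize(tab, cfg)
  r2 <- advanced_equalize(tab, cfg)
  expect_identical(r1$kept_ids, r2$kept_ids)
  expect_identical(r1$size_trace, r2$size_trace)
  r3 <- advanced_equalize(tab, equalize_config("advanced",
                                               variables = c("exposure", "age"),
                                               seed = 10))
  expect_false(identical(r1$kept_ids, r3$kept_ids))
})

test_that("sanity check detects overlap and loss", {
  fake <- function(kept, removed)
    structure(list(kept_ids = kept, removed_ids = removed),
              class = "equalize_result")
  expect_true(sanity_check(c("1", "2", "3"), fake(c("1", "2"), "3")))
  expect_false(sanity_check(c("1", "2", "3"), fake(c("1", "2"), c("2", "3"))))
  expect_false(sanity_check(c("1", "2", "3"), fake("1", "3")))
})

test_that("every method yields a partition and non-increasing impact", {
  tab <- standard_confounded_fixture(6)
  ids <- sample_ids(tab)
  vars <- c("exposure", "sex")
  for (m in c("samples", "proportions", "advanced")) {
    cfg <- equalize_config(m, variables = vars, seed = 4, bypass = TRUE)
    res <- equalize(tab, cfg)
    expect_true(sanity_check(ids, res))
    if (m != "samples")
      expect_lte(res$impact_final, sum(res$impact_scores) + 1e-12)
  }
})
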