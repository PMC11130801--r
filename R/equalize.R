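#' Cohort equalization
#'
#' Three seeded, removal-based balancing algorithms operate on a cohort
#' table with roles assigned:
#'
#' * `equalize_samples()` — uniform random downsampling of every
#'   subpopulation to the size of the smallest one.
#' * `equalize_proportions()` — greedy single-sample removals chosen to
#'   reduce the total impact score of the configured variables, until every
#'   configured variable tests non-significant between groups (p > alpha),
#'   no removal improves balance, or the iteration cap is hit. The relative
#'   size ordering of subpopulations is preserved.
#' * `advanced_equalize()` — the hybrid: impact scores rank the variables,
#'   a size phase brings every subpopulation down to the smallest one while
#'   steering each removal to keep the highest-impact variable's group
#'   proportions close to the pooled proportions, and a fine-tuning phase
#'   then continues impact-reducing removals from any subpopulation above
#'   the minimum-size threshold until no single removal helps.
#'
#' Protected identifiers are never removed, and a subpopulation at or below
#' `min_threshold` accepts no further removals. All randomness (tie-breaks,
#' uniform downsampling) flows from the configured seed, so identical input
#' and configuration reproduce identical results.
#'
#' @name equalization
NULL

#' Equalization configuration
#'
#' @param method one of `"samples"`, `"proportions"`, `"advanced"`
#' @param variables feature names balanced by the proportion-aware methods
#'   (required for `"proportions"` and `"advanced"`)
#' @param bypass if `TRUE` the smallest subpopulation is also eligible for
#'   removals (aggressive mode); if `FALSE` it is exempt
#' @param min_threshold minimum subpopulation size; no removal may take a
#'   group at or below this size any lower (default 5)
#' @param seed positive integer (>= 1) driving all randomness
#' @param protected_ids identifiers pinned into the kept set
#' @param alpha significance level for the proportion-balance stopping rule
#' @param max_iterations cap on removal steps / sweeps (default 10x the
#'   number of samples, resolved at run time)
#' @return an `equalize_config`
#' @export
equalize_config <- function(method = c("samples", "proportions", "advanced"),
                            variables = character(),
                            bypass = FALSE,
                            min_threshold = 5L,
                            seed = 1L,
                            protected_ids = character(),
                            alpha = 0.05,
                            max_iterations = NULL) {
  method <- match.arg(method)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 1)
    cohorteq_error("cohorteq_bad_seed", "seed must be a single integer >= 1")
  if (method %in% c("proportions", "advanced") && length(variables) == 0L)
    cohorteq_error("cohorteq_bad_config",
                   paste0("method '", method, "' needs a non-empty variable list"))
  if (min_threshold < 0)
    cohorteq_error("cohorteq_bad_config", "min_threshold must be >= 0")
  structure(list(method = method, variables = as.character(variables),
                 bypass = isTRUE(bypass), min_threshold = as.integer(min_threshold),
                 seed = as.integer(seed),
                 protected_ids = as.character(protected_ids),
                 alpha = alpha, max_iterations = max_iterations),
            class = "equalize_config")
}

# ---- impact scores -------------------------------------------------------

# Category index per sample for one variable: categorical variables use
# their observed categories; continuous variables are binned into pooled
# quartiles (computed once, on the full table, and held fixed during
# removals). Missing cells form their own bin so counts always sum to the
# subpopulation size.
categorize_variable <- function(values, kind) {
  if (kind == "continuous") {
    num <- parse_number(values)
    breaks <- unique(stats::quantile(num[!is.na(num)],
                                     c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                                     type = 7))
    if (length(breaks) < 2L) breaks <- c(breaks, breaks + 1)
    binned <- cut(num, breaks = breaks, include.lowest = TRUE)
    lv <- c(levels(binned), "(missing)")
    idx <- as.integer(binned)
  } else {
    f <- factor(values)
    lv <- c(levels(f), "(missing)")
    idx <- as.integer(f)
  }
  idx[is.na(idx)] <- length(lv)
  list(index = idx, levels = lv)
}

balance_state <- function(table, variables, specs, protected_ids) {
  unknown <- setdiff(variables, names(table$data))
  if (length(unknown))
    cohorteq_error("cohorteq_unknown_variable",
                   paste0("unknown variable(s): ", paste(unknown, collapse = ", ")))
  ids <- sample_ids(table)
  missing_prot <- setdiff(protected_ids, ids)
  if (length(missing_prot))
    cohorteq_error("cohorteq_unknown_identifier",
                   paste0("protected id(s) not in the table: ",
                          paste(utils::head(missing_prot, 5L), collapse = ", ")))
  groups <- factor(table$data[[table$target_column]])
  cat_info <- lapply(variables, function(v)
    categorize_variable(table$data[[v]], specs[[v]]$kind))
  names(cat_info) <- variables
  sizes <- as.integer(table(groups))
  names(sizes) <- levels(groups)
  counts <- lapply(cat_info, function(ci) {
    m <- matrix(0L, nrow = nlevels(groups), ncol = length(ci$levels),
                dimnames = list(levels(groups), ci$levels))
    tab <- table(groups, ci$index)
    m[, as.integer(colnames(tab))] <- as.integer(tab)
    m
  })
  list(ids = ids,
       groups = groups,
       kept = rep(TRUE, length(ids)),
       protected = ids %in% protected_ids,
       catidx = lapply(cat_info, `[[`, "index"),
       counts = counts,
       sizes = sizes,
       orig_sizes = sizes)
}

variable_impact_from_counts <- function(mat, sizes) {
  active <- sizes > 0
  if (!any(active) || sum(mat) == 0) return(0)
  pool <- colSums(mat) / sum(mat)
  sum(vapply(which(active), function(g)
    0.5 * sum(abs(mat[g, ] / sizes[g] - pool)), numeric(1)))
}

state_impacts <- function(state) {
  vapply(names(state$counts), function(v)
    variable_impact_from_counts(state$counts[[v]], state$sizes), numeric(1))
}

apply_removal <- function(state, idx) {
  g <- as.integer(state$groups[idx])
  state$kept[idx] <- FALSE
  state$sizes[g] <- state$sizes[g] - 1L
  for (v in names(state$counts)) {
    c_idx <- state$catidx[[v]][idx]
    state$counts[[v]][g, c_idx] <- state$counts[[v]][g, c_idx] - 1L
  }
  state
}

# Impact change (for `objective`: "total" or one variable name) if one
# sample of group g with the given per-variable categories is removed.
removal_delta <- function(state, g, cats, objective) {
  new_sizes <- state$sizes
  new_sizes[g] <- new_sizes[g] - 1L
  vars <- if (identical(objective, "total")) names(state$counts) else objective
  delta <- 0
  for (v in vars) {
    mat <- state$counts[[v]]
    before <- variable_impact_from_counts(mat, state$sizes)
    mat[g, cats[[v]]] <- mat[g, cats[[v]]] - 1L
    after <- variable_impact_from_counts(mat, new_sizes)
    delta <- delta + (after - before)
  }
  delta
}

# Find the best single-sample removal among `eligible_groups` (group level
# indices). Candidates with identical (group, category-profile) have equal
# deltas, so evaluation runs per distinct profile. Ties among best samples
# are broken uniformly at random over lexicographically sorted identifiers
# (seeded by the caller).
best_removal <- function(state, eligible_groups, objective = "total") {
  cand <- which(state$kept & !state$protected &
                  as.integer(state$groups) %in% eligible_groups)
  if (length(cand) == 0L) return(NULL)
  profile <- vapply(cand, function(i)
    paste(as.integer(state$groups[i]),
          paste(vapply(names(state$catidx), function(v)
            state$catidx[[v]][i], integer(1)), collapse = "|"),
          sep = "@"), character(1))
  reps <- cand[!duplicated(profile)]
  deltas <- vapply(reps, function(i) {
    g <- as.integer(state$groups[i])
    cats <- lapply(state$catidx, `[[`, i)
    removal_delta(state, g, cats, objective)
  }, numeric(1))
  best <- min(deltas)
  best_profiles <- unique(profile[!duplicated(profile)][deltas <= best + 1e-12])
  pool <- cand[profile %in% best_profiles]
  pool <- pool[order(state$ids[pool])]
  pick <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), 1L)]
  list(index = pick, delta = best)
}

#' Impact scores: deviation of per-group proportions from pooled expectation
#'
#' For each variable the per-subpopulation category distribution is
#' compared with the pooled distribution using total variation distance;
#' the score sums those distances over subpopulations. Continuous variables
#' are binned into pooled quartiles first. A variable distributed
#' identically in every subpopulation scores 0; a binary variable that
#' perfectly separates two equal-sized groups scores 1.
#'
#' @param table a [cohort_table()] with roles assigned
#' @param variables feature names to score
#' @param specs variable specs (recomputed if omitted)
#' @return named numeric vector, sorted in decreasing order
#' @export
compute_impact_scores <- function(table, variables, specs = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  specs <- specs %||% infer_variable_types(table)
  state <- balance_state(table, variables, specs, character())
  sort(state_impacts(state), decreasing = TRUE)
}

# ---- results -------------------------------------------------------------

finalize_result <- function(table, config, state, impact_initial, iterations,
                            trace, flags, specs) {
  kept_ids <- state$ids[state$kept]
  removed_ids <- state$ids[!state$kept]
  kept_table <- subset_ids(table, kept_ids)
  summarize <- function(tbl) {
    lapply(stats::setNames(config$variables, config$variables), function(v) {
      list(describe = tryCatch(describe_variable(tbl, v, specs), error = function(e) NULL),
           test = tryCatch(select_test(tbl, v, specs, alpha = config$alpha),
                           error = function(e) NULL))
    })
  }
  structure(list(kept_ids = kept_ids,
                 removed_ids = removed_ids,
                 target_size = min(state$orig_sizes),
                 impact_scores = impact_initial,
                 impact_final = if (length(config$variables)) sum(state_impacts(state)) else 0,
                 iterations_run = iterations,
                 size_trace = trace,
                 sizes_before = state$orig_sizes,
                 sizes_after = state$sizes,
                 flags = flags,
                 before_summary = if (length(config$variables)) summarize(table) else list(),
                 after_summary = if (length(config$variables)) summarize(kept_table) else list(),
                 config = config),
            class = "equalize_result")
}

#' @export
print.equalize_result <- function(x, ...) {
  cat(sprintf("<equalize_result> method=%s: kept %d, removed %d (seed %d)\n",
              x$config$method, length(x$kept_ids), length(x$removed_ids),
              x$config$seed))
  cat("  sizes before:", paste(sprintf("%s=%d", names(x$sizes_before),
                                       x$sizes_before), collapse = ", "), "\n")
  cat("  sizes after: ", paste(sprintf("%s=%d", names(x$sizes_after),
                                       x$sizes_after), collapse = ", "), "\n")
  if (length(x$impact_scores))
    cat("  impact (initial):",
        paste(sprintf("%s=%.3f", names(x$impact_scores), x$impact_scores),
              collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Partition sanity check
#'
#' Verifies that the kept and removed identifier sets are disjoint and
#' jointly recover the original identifiers exactly.
#'
#' @param original_ids identifiers of the input table
#' @param result an `equalize_result`
#' @return `TRUE` iff kept/removed partition `original_ids`
#' @export
sanity_check <- function(original_ids, result) {
  kept <- result$kept_ids
  removed <- result$removed_ids
  length(intersect(kept, removed)) == 0L &&
    setequal(c(kept, removed), original_ids) &&
    length(kept) + length(removed) == length(original_ids)
}

# ---- methods -------------------------------------------------------------

#' Equalize subpopulation sizes by uniform downsampling
#'
#' Every subpopulation is downsampled, uniformly at random under the
#' configured seed, to the size of the smallest one. Protected samples are
#' never removed; if a subpopulation holds more protected samples than the
#' target size it ends larger, and the result is flagged.
#'
#' @param table a [cohort_table()] with roles assigned
#' @param config an [equalize_config()] (`method = "samples"`)
#' @return an `equalize_result`
#' @export
equalize_samples <- function(table, config = equalize_config("samples")) {
  stopifnot(inherits(table, "cohort_table"), inherits(config, "equalize_config"))
  specs <- infer_variable_types(table)
  state <- balance_state(table, config$variables, specs, config$protected_ids)
  target <- min(state$sizes)
  flags <- character()
  smallest <- names(state$sizes)[which.min(state$sizes)]
  with_seed(config$seed, {
    for (g in sort(names(state$sizes))) {
      excess <- state$sizes[[g]] - target
      if (excess <= 0L) next
      if (!config$bypass && identical(g, smallest)) next
      in_group <- which(state$kept & state$groups == g & !state$protected)
      n_protected <- sum(state$groups == g & state$protected)
      if (n_protected > target) {
        excess <- state$sizes[[g]] - n_protected
        flags <- c(flags, sprintf(
          "subpopulation '%s' has %d protected samples; kept above target size %d",
          g, n_protected, target))
      }
      if (excess <= 0L) next
      cand <- in_group[order(state$ids[in_group])]
      drop <- if (length(cand) == excess) cand
              else cand[sample.int(length(cand), excess)]
      for (idx in drop) state <- apply_removal(state, idx)
    }
  })
  impacts <- if (length(config$variables))
    sort(state_impacts(balance_state(table, config$variables, specs,
                                     config$protected_ids)), decreasing = TRUE)
  else numeric()
  finalize_result(table, config, state, impacts,
                  iterations = 1L,
                  trace = list(state$sizes), flags = flags, specs = specs)
}

eligible_group_indices <- function(state, config, enforce_order = TRUE) {
  lv <- levels(state$groups)
  ok <- vapply(seq_along(lv), function(g) {
    size <- state$sizes[[g]]
    if (size <= config$min_threshold) return(FALSE)
    # bypass = FALSE exempts the (originally) smallest subpopulation(s)
    if (!config$bypass && state$orig_sizes[[g]] == min(state$orig_sizes))
      return(FALSE)
    if (enforce_order) {
      smaller <- which(state$orig_sizes < state$orig_sizes[[g]])
      if (length(smaller) && any(size - 1L < state$sizes[smaller])) return(FALSE)
    }
    any(state$kept & !state$protected & as.integer(state$groups) == g)
  }, logical(1))
  which(ok)
}

balance_verdict <- function(table, state, config, specs) {
  kept_table <- subset_ids(table, state$ids[state$kept])
  for (v in config$variables) {
    res <- tryCatch(select_test(kept_table, v, specs, alpha = config$alpha),
                    error = function(e) NULL)
    if (!is.null(res) && !is.na(res$p_value) && res$p_value <= config$alpha)
      return(sprintf("imbalance remains: '%s' still significant (p = %s)",
                     v, format_p(res$p_value)))
  }
  "balanced: all configured variables non-significant (p > alpha)"
}

#' Equalize covariate proportions across subpopulations
#'
#' Greedy iterative removal: at each step every candidate single-sample
#' removal (excluding protected samples and, unless `bypass`, the smallest
#' subpopulation) is scored by its effect on the summed impact score of the
#' configured variables, and the most balance-improving one is applied.
#' Iteration continues until no removal strictly reduces total impact (a
#' greedy balance optimum) or `max_iterations` is reached; the result's
#' flags then record whether every configured variable's between-group test
#' came out non-significant (p > alpha). A cohort that is already balanced
#' admits no improving removal, so nothing is removed. Subpopulation
#' relative size ordering is preserved throughout.
#'
#' @param table a [cohort_table()] with roles assigned
#' @param config an [equalize_config()] (`method = "proportions"`)
#' @return an `equalize_result`
#' @export
equalize_proportions <- function(table, config) {
  stopifnot(inherits(table, "cohort_table"), inherits(config, "equalize_config"))
  if (length(config$variables) == 0L)
    cohorteq_error("cohorteq_bad_config", "proportions method needs variables")
  specs <- infer_variable_types(table)
  state <- balance_state(table, config$variables, specs, config$protected_ids)
  impact_initial <- sort(state_impacts(state), decreasing = TRUE)
  max_iter <- config$max_iterations %||% (10L * length(state$ids))
  trace <- list(state$sizes)
  iter <- 0L
  flags <- character()
  with_seed(config$seed, {
    while (iter < max_iter) {
      mv <- best_removal(state, eligible_group_indices(state, config), "total")
      if (is.null(mv) || mv$delta >= -1e-12) {
        flags <- c(flags, "stopped: no removal reduces total impact")
        break
      }
      state <- apply_removal(state, mv$index)
      iter <- iter + 1L
      trace[[length(trace) + 1L]] <- state$sizes
    }
  })
  if (iter >= max_iter) flags <- c(flags, "stopped: max_iterations reached")
  flags <- c(flags, balance_verdict(table, state, config, specs))
  finalize_result(table, config, state, impact_initial, iter, trace, flags, specs)
}

#' Hybrid (advanced) equalization
#'
#' Impact scores rank the configured variables; the algorithm then works in
#' two phases. The size phase sweeps the ranked variables, removing from
#' each oversized subpopulation the sample whose removal best moves that
#' variable's subpopulation proportions toward the pooled proportions,
#' until every subpopulation matches the size of the smallest. The
#' fine-tuning phase continues with greedy total-impact-reducing removals
#' from any subpopulation still above `min_threshold` — including the
#' smallest — until no single removal improves balance. This trades some
#' additional sample loss for tighter proportion alignment, which is the
#' point of the hybrid method.
#'
#' @param table a [cohort_table()] with roles assigned
#' @param config an [equalize_config()] (`method = "advanced"`)
#' @return an `equalize_result`
#' @export
advanced_equalize <- function(table, config) {
  stopifnot(inherits(table, "cohort_table"), inherits(config, "equalize_config"))
  if (length(config$variables) == 0L)
    cohorteq_error("cohorteq_bad_config", "advanced method needs variables")
  specs <- infer_variable_types(table)
  state <- balance_state(table, config$variables, specs, config$protected_ids)
  target <- min(state$sizes)
  if (config$min_threshold > target)
    cohorteq_error("cohorteq_bad_threshold",
                   sprintf("min_threshold (%d) exceeds the smallest subpopulation (%d)",
                           config$min_threshold, target))
  impact_initial <- sort(state_impacts(state), decreasing = TRUE)
  vars_sorted <- names(impact_initial)
  max_iter <- config$max_iterations %||% (10L * length(state$ids))
  trace <- list(state$sizes)
  removals <- 0L
  sweeps <- 0L
  flags <- character()
  with_seed(config$seed, {
    # Phase 1: bring every subpopulation to the target size, steering each
    # removal by the highest-impact variables first.
    while (any(state$sizes > target) && sweeps < max_iter) {
      progressed <- FALSE
      for (v in vars_sorted) {
        for (g in which(state$sizes > target)) {
          if (state$sizes[[g]] <= config$min_threshold) next
          mv <- best_removal(state, g, v)
          if (is.null(mv)) next
          state <- apply_removal(state, mv$index)
          removals <- removals + 1L
          progressed <- TRUE
          if (!any(state$sizes > target)) break
        }
        if (!any(state$sizes > target)) break
      }
      sweeps <- sweeps + 1L
      trace[[length(trace) + 1L]] <- state$sizes
      if (!progressed) {
        flags <- c(flags, "size phase stalled: remaining samples protected")
        break
      }
    }
    # Phase 2: proportion fine-tuning across all subpopulations.
    while (removals < max_iter) {
      eligible <- which(state$sizes > config$min_threshold)
      eligible <- eligible[vapply(eligible, function(g)
        any(state$kept & !state$protected & as.integer(state$groups) == g),
        logical(1))]
      if (length(eligible) == 0L) break
      mv <- best_removal(state, eligible, "total")
      if (is.null(mv) || mv$delta >= -1e-12) break
      state <- apply_removal(state, mv$index)
      removals <- removals + 1L
      trace[[length(trace) + 1L]] <- state$sizes
    }
  })
  if (removals >= max_iter) flags <- c(flags, "stopped: max_iterations reached")
  flags <- c(flags, balance_verdict(table, state, config, specs))
  finalize_result(table, config, state, impact_initial, removals, trace,
                  flags, specs)
}

#' Run the configured equalization method
#'
#' Dispatches to [equalize_samples()], [equalize_proportions()] or
#' [advanced_equalize()] and verifies the kept/removed partition with
#' [sanity_check()] before returning.
#'
#' @param table a [cohort_table()] with roles assigned
#' @param config an [equalize_config()]
#' @return an `equalize_result`
#' @export
equalize <- function(table, config) {
  result <- switch(config$method,
                   samples = equalize_samples(table, config),
                   proportions = equalize_proportions(table, config),
                   advanced = advanced_equalize(table, config))
  if (!sanity_check(sample_ids(table), result))
    cohorteq_error("cohorteq_sanity_failure",
                   "kept/removed sets do not partition the input identifiers")
  result
}
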