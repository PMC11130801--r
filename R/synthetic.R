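#' Synthetic case/control cohorts
#'
#' Seeded generator of rectangular cohorts in the shape this package
#' consumes: sequential identifiers, a target column with exact per-group
#' sizes, categorical features drawn from per-group probability vectors,
#' continuous features from per-group location/scale families (a normal
#' family, plus a right-skewed exponential family so both branches of the
#' normality gate are exercisable), and uniform missingness per feature.
#'
#' @name synthetic_data
NULL

#' Specification of a synthetic cohort
#'
#' @param group_sizes named integer vector (2-15 groups), e.g.
#'   `c(case = 112, control = 103)`
#' @param categorical named list; each element is a list with `levels`
#'   (category labels) and `probs`, a named list mapping each group to a
#'   probability vector over `levels` (must sum to 1 within 1e-9)
#' @param continuous named list; each element is a list with `location` and
#'   `scale` (named numeric vectors per group, or scalars recycled to all
#'   groups) and optional `family` (`"normal"`, the default, or `"skewed"`
#'   for a location-shifted exponential)
#' @param missing_rate single rate in \[0,1) applied to every feature, or a
#'   named vector per feature
#' @param seed positive integer (>= 1)
#' @return a `synthetic_spec`
#' @export
synthetic_spec <- function(group_sizes, categorical = list(),
                           continuous = list(), missing_rate = 0, seed = 1L) {
  if (length(group_sizes) < 2L || length(group_sizes) > 15L)
    cohorteq_error("cohorteq_bad_spec", "need between 2 and 15 groups")
  if (is.null(names(group_sizes)) || anyDuplicated(names(group_sizes)))
    cohorteq_error("cohorteq_bad_spec", "group_sizes must have unique names")
  groups <- names(group_sizes)
  for (v in names(categorical)) {
    cv <- categorical[[v]]
    for (g in groups) {
      p <- cv$probs[[g]]
      if (is.null(p) || length(p) != length(cv$levels))
        cohorteq_error("cohorteq_bad_spec",
                       sprintf("variable '%s': missing/ragged probabilities for group '%s'",
                               v, g))
      if (abs(sum(p) - 1) > 1e-9)
        cohorteq_error("cohorteq_bad_spec",
                       sprintf("variable '%s', group '%s': probabilities sum to %g, not 1",
                               v, g, sum(p)))
    }
  }
  if (any(missing_rate < 0 | missing_rate >= 1))
    cohorteq_error("cohorteq_bad_spec", "missing_rate must be in [0, 1)")
  structure(list(group_sizes = group_sizes, categorical = categorical,
                 continuous = continuous, missing_rate = missing_rate,
                 seed = seed),
            class = "synthetic_spec")
}

recycle_param <- function(p, groups) {
  if (length(p) == 1L && is.null(names(p)))
    return(stats::setNames(rep(p, length(groups)), groups))
  p[groups]
}

#' Generate a cohort table from a synthetic specification
#'
#' @param spec a [synthetic_spec()]
#' @return a [cohort_table()] with roles assigned (`sample_id`, `group`)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  groups <- names(spec$group_sizes)
  n <- sum(spec$group_sizes)
  target <- rep(groups, times = spec$group_sizes)
  df <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                   group = target, stringsAsFactors = FALSE)
  with_seed(spec$seed, {
    for (v in names(spec$categorical)) {
      cv <- spec$categorical[[v]]
      col <- character(n)
      for (g in groups) {
        idx <- which(target == g)
        col[idx] <- sample(cv$levels, length(idx), replace = TRUE,
                           prob = cv$probs[[g]])
      }
      df[[v]] <- col
    }
    for (v in names(spec$continuous)) {
      cv <- spec$continuous[[v]]
      loc <- recycle_param(cv$location, groups)
      scl <- recycle_param(cv$scale, groups)
      family <- cv$family %||% "normal"
      col <- numeric(n)
      for (g in groups) {
        idx <- which(target == g)
        col[idx] <- if (family == "skewed")
          loc[[g]] + stats::rexp(length(idx), rate = 1 / scl[[g]])
        else
          stats::rnorm(length(idx), mean = loc[[g]], sd = scl[[g]])
      }
      df[[v]] <- format(round(col, 4), trim = TRUE, scientific = FALSE)
    }
    features <- setdiff(names(df), c("sample_id", "group"))
    rates <- if (length(spec$missing_rate) == 1L)
      stats::setNames(rep(spec$missing_rate, length(features)), features)
    else spec$missing_rate
    for (v in features) {
      r <- rates[[v]] %||% 0
      if (r > 0) {
        hide <- stats::runif(n) < r
        df[[v]][hide] <- NA
      }
    }
  })
  validate_roles(cohort_table(df), target = "group", identifier = "sample_id")
}

#' The standard confounded test cohort
#'
#' A canonical two-group cohort for exercising the equalizers: 150 cases
#' and 100 controls; a binary confounder (`exposure`) at 70% prevalence in
#' cases versus 30% in controls; a balanced binary variable (`sex`,
#' 50%/50% in both groups); a continuous variable (`age`) shifted by one
#' pooled standard deviation between groups (cases N(67, 12), controls
#' N(55, 12)); and 5% missingness in each feature. Always 250 rows.
#'
#' @param seed positive integer (>= 1)
#' @return a [cohort_table()] with roles assigned
#' @export
standard_confounded_fixture <- function(seed = 1L) {
  spec <- synthetic_spec(
    group_sizes = c(case = 150L, control = 100L),
    categorical = list(
      exposure = list(levels = c("no", "yes"),
                      probs = list(case = c(0.3, 0.7), control = c(0.7, 0.3))),
      sex = list(levels = c("female", "male"),
                 probs = list(case = c(0.5, 0.5), control = c(0.5, 0.5)))),
    continuous = list(
      age = list(location = c(case = 67, control = 55),
                 scale = c(case = 12, control = 12))),
    missing_rate = 0.05,
    seed = seed)
  generate_cohort(spec)
}
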