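#' @keywords internal
"_PACKAGE"

# Tokens treated as missing on input, compared case-insensitively.
MISSING_TOKENS <- c("", "na", "nan", "n/a", "null")

`%||%` <- function(x, y) if (is.null(x)) y else x

cohorteq_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "cohorteq_error")))
}

#' Parse cell text as numbers
#'
#' Accepts plain decimal notation with a `.` separator (scientific notation
#' included); anything else -- including locale variants such as `1,5` --
#' yields `NA` so the column falls back to categorical handling.
#'
#' @param x character vector of cell values
#' @return numeric vector with `NA` where the text is not a number
#' @keywords internal
parse_number <- function(x) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  # as.numeric() accepts hex ("0x1F") and "Inf"; neither is table data here
  bad <- grepl("x|inf", x, ignore.case = TRUE)
  out[bad] <- NA_real_
  out
}

is_missing_cell <- function(x) {
  is.na(x) | tolower(trimws(x)) %in% MISSING_TOKENS
}

normalize_missing <- function(x) {
  x[is_missing_cell(x)] <- NA_character_
  x
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic behaviour in the package
# funnels through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 1)
    cohorteq_error("cohorteq_bad_seed", "seed must be a single integer >= 1")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Round half away from zero (so 8397.9 -> 8398, 0.5 -> 1), unlike base
# round()'s round-half-even.
round_half_up <- function(x) floor(x + 0.5)

#' Format a p-value for display
#'
#' Three decimals; values below 0.0005 are rendered `<0.001`.
#'
#' @param p numeric vector of p-values
#' @return character vector
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.0005, "<0.001", sprintf("%.3f", p)))
}
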