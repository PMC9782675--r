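#' Round half away from zero
#'
#' Presentation rounding used for reported percentages: exact halves round up
#' in magnitude (`round_half_up(2.45, 1)` is 2.5), unlike [base::round()]'s
#' banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count over a denominator, rounded for reporting
#'
#' @param count Event count(s).
#' @param denom Denominator(s); must be positive.
#' @param digits Decimal places (default 1, the registry-table convention).
#' @return Numeric percentage(s), half-up rounded.
#' @export
pct <- function(count, denom, digits = 1) {
  stopifnot(all(denom > 0))
  round_half_up(100 * count / denom, digits)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same subjects;
#' 1 for identical partitions (up to relabeling), about 0 for independent ones.
#'
#' @param a,b Integer or factor label vectors of equal length.
#' @return Scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Derive a stream of per-iteration seeds from one master seed; documented
# counter scheme so resampling loops are reproducible (and parallelizable)
# without sharing RNG state.
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
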