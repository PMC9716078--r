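#' Round half away from zero
#'
#' Standard "commercial" rounding used when formatting summary tables: 0.05
#' rounds up to 0.1, unlike [base::round()]'s round-half-even. Used for every
#' percentage and decimal printed by [summarize_cohort()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.05, 0.15, 56.25), 1)
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Pool stratum counts into a percentage
#'
#' Combines per-stratum counts (e.g. per-drug cells of a demographics table)
#' into the pooled percentage, rounded half-up to one decimal.
#'
#' @param counts integer vector of per-stratum numerators.
#' @param totals integer vector of per-stratum denominators (recycled if
#'   length 1).
#' @param digits decimals for rounding (default 1).
#' @return a single pooled percentage.
#' @export
#' @examples
#' pooled_percent(c(177, 86, 164, 2), c(317, 150, 287, 3)) # 56.7
pooled_percent <- function(counts, totals, digits = 1) {
  stopifnot(all(counts >= 0), all(totals > 0))
  round_half_up(100 * sum(counts) / sum(rep_len(totals, length(counts))), digits)
}

#' Pool stratum means into a count-weighted mean
#'
#' @param means per-stratum means.
#' @param weights per-stratum counts.
#' @param digits decimals for rounding (default 1).
#' @return count-weighted pooled mean.
#' @export
#' @examples
#' pooled_mean(c(55.2, 56.4, 57.1, 63.3), c(317, 150, 287, 3)) # 56.2
pooled_mean <- function(means, weights, digits = 1) {
  stopifnot(length(means) == length(weights), all(weights >= 0), sum(weights) > 0)
  round_half_up(sum(means * weights) / sum(weights), digits)
}

# Normalize free-text terms for matching: lower-case, squeeze whitespace.
normalize_term <- function(x) {
  stringr::str_squish(tolower(x))
}

# TRUE for drug-name strings containing any of the given ingredient/brand
# substrings (case-insensitive, whitespace-normalized). FAERS drugname is
# free text, hence substring rather than exact matching.
matches_any_substring <- function(x, patterns) {
  xn <- normalize_term(x)
  hit <- rep(FALSE, length(xn))
  for (p in normalize_term(patterns)) {
    hit <- hit | stringr::str_detect(xn, stringr::fixed(p))
  }
  hit & !is.na(xn)
}

# Truncated-normal sampler via inverse-CDF; vectorized over per-draw bounds.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}
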