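#' @include utils-belt.R
NULL

# Self-contained statistical utilities used throughout the reports:
# 2x2 chi-squared with continuity correction, Benjamini-Hochberg FDR,
# bootstrap median-difference estimation, and permutation-percentile
# verdicts.

#' 2x2 chi-squared test with Yates continuity correction
#'
#' \deqn{\chi^2 = \sum (|O - E| - 0.5)^2 / E} with expected counts from
#' the margins; df = 1. The uncorrected variant is exposed via `correct`.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param correct apply the continuity correction (default TRUE).
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @examples
#' # proportions 169/444 vs 1581/4928
#' chiSquaredYates(matrix(c(169, 275, 1581, 3347), 2, byrow = TRUE))
#' @export
chiSquaredYates <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin: chi-squared undefined")
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment, monotone in rank order and capped at 1.
#'
#' @param p vector of p-values in [0, 1] (empty input allowed).
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Bootstrap estimate of a median difference
#'
#' Resamples both groups with replacement `n` times, recording
#' median(b) - median(a); the 95% CI is the 2.5/97.5 percentile of the
#' resample distribution.
#'
#' @param a,b numeric samples.
#' @param n number of bootstrap resamples.
#' @param seed RNG seed.
#' @return list with `estimate` (observed median difference),
#'   `distribution`, `ci` (length 2).
#' @export
bootstrapMedianDifference <- function(a, b, n = 5000, seed = 1) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  set.seed(childSeed(seed, 0))
  dist <- vapply(seq_len(n), function(i) {
    stats::median(sample(b, replace = TRUE)) -
      stats::median(sample(a, replace = TRUE))
  }, numeric(1))
  list(estimate = stats::median(b) - stats::median(a),
       distribution = dist,
       ci = stats::quantile(dist, c(0.025, 0.975), names = FALSE))
}

#' Exceedance percentile of an observation within a permutation null
#'
#' @param observed observed statistic.
#' @param nullSamples permutation null samples (at least 100 for the 95th
#'   cutoff, at least 1000 for the 99.9th).
#' @param cutoffs percentile cutoffs at which verdicts are returned.
#' @return list with `percentile` (of `observed` within the null) and
#'   `verdicts` (named logical: observed exceeds each cutoff's null
#'   quantile).
#' @export
permutationPercentile <- function(observed, nullSamples,
                                  cutoffs = c(95, 99.9)) {
  need <- ifelse(cutoffs >= 99.9, 1000, 100)
  if (length(nullSamples) < max(need))
    stop("need at least ", max(need), " null samples for the ",
         max(cutoffs), "th percentile cutoff")
  perc <- 100 * mean(nullSamples < observed)
  verdicts <- vapply(cutoffs, function(cp)
    observed > stats::quantile(nullSamples, cp / 100, names = FALSE),
    logical(1))
  names(verdicts) <- paste0("p", cutoffs)
  list(percentile = perc, verdicts = verdicts)
}
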