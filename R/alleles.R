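# Allele-fixation classification of per-position RNA-seq counts: a position
# is "fixed" when one allele strictly exceeds the threshold fraction of all
# nucleotides sequenced there, otherwise both alleles are being expressed.

#' Classify allele fixation at single positions
#'
#' Applies the strict majority rule: with `total = wt + var + other`, a
#' position is `wt_fixed` when `wt / total > threshold`, `variant_fixed`
#' when `var / total > threshold`, and `heterogeneous` otherwise (so a
#' position at exactly the threshold fraction counts as heterogeneous).
#' Other-base reads stay in the denominator — they are part of the
#' nucleotides sequenced at the position.  Positions with fewer than
#' `min_depth` reads are `low_depth`.
#'
#' @param wt_count,var_count,other_count Read counts (vectors recycle).
#' @param threshold Fixation fraction in (0.5, 1); default 0.9, i.e. the
#'   ">90%" rule.
#' @param min_depth Minimum total reads to classify (default 1).
#' @return A character vector in `{wt_fixed, variant_fixed,
#'   heterogeneous, low_depth}`.
#' @examples
#' classify_fixation(95, 5)        # wt_fixed
#' classify_fixation(90, 10)       # heterogeneous: 90% is not > 90%
#' @export
classify_fixation <- function(wt_count, var_count, other_count = 0,
                              threshold = 0.9, min_depth = 1) {
  if (!(threshold > 0.5 && threshold < 1)) {
    abort("`threshold` must be in (0.5, 1)")
  }
  if (min_depth < 1) abort("`min_depth` must be >= 1")
  n <- max(length(wt_count), length(var_count), length(other_count))
  wt <- rep_len(wt_count, n)
  var <- rep_len(var_count, n)
  oth <- rep_len(other_count, n)
  if (any(wt < 0 | var < 0 | oth < 0)) abort("allele counts must be >= 0")
  total <- wt + var + oth
  out <- rep("heterogeneous", n)
  out[wt / total > threshold] <- "wt_fixed"
  out[var / total > threshold] <- "variant_fixed"
  out[total < min_depth] <- "low_depth"
  out
}

#' Summarize allele fixation over a set of positions
#'
#' @param counts A tibble of allele counts with columns `wt_count`,
#'   `var_count` and optionally `other_count` (e.g. from
#'   [read_allele_counts()] or [simulate_allele_counts()]).
#' @param threshold,min_depth Passed to [classify_fixation()].
#' @return A one-row tibble with `n_wt_fixed`, `n_variant_fixed`,
#'   `n_heterogeneous`, `n_low_depth` and `n_total`; the first four sum
#'   to the total.
#' @export
summarize_fixation <- function(counts, threshold = 0.9, min_depth = 1) {
  stopifnot(is.data.frame(counts))
  if (nrow(counts) == 0) abort("`counts` must be non-empty")
  oth <- if ("other_count" %in% names(counts)) counts$other_count else 0
  cls <- classify_fixation(counts$wt_count, counts$var_count, oth,
                           threshold = threshold, min_depth = min_depth)
  tibble(
    n_wt_fixed = sum(cls == "wt_fixed"),
    n_variant_fixed = sum(cls == "variant_fixed"),
    n_heterogeneous = sum(cls == "heterogeneous"),
    n_low_depth = sum(cls == "low_depth"),
    n_total = length(cls)
  )
}
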