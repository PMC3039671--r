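# broom-style accessors for fitted results.

#' Tidy a peak call
#'
#' @param x A `peak_call` from [call_peaks()].
#' @param ... Unused.
#' @return The peak tibble (one row per called region).
#' @export
tidy.peak_call <- function(x, ...) {
  x$peaks
}

#' One-row summary of a peak call
#'
#' @param x A `peak_call` from [call_peaks()].
#' @param ... Unused.
#' @return A one-row tibble: mode, target FDR, calibrated cutoff,
#'   region count, covered bp, mean maximum height and the number of
#'   background segments applied.
#' @export
glance.peak_call <- function(x, ...) {
  tibble(
    mode = x$config$mode,
    fdr = x$config$fdr,
    height_cutoff = x$calibration$height_cutoff,
    n_regions = nrow(x$peaks),
    total_bp = sum(x$peaks$end - x$peaks$start),
    mean_max_height = if (nrow(x$peaks) > 0) mean(x$peaks$max_height) else NA_real_,
    n_segments = nrow(x$segments)
  )
}

#' Tidy an FDR calibration
#'
#' @param x An `fdr_calibration` from [calibrate_height_cutoff()].
#' @param ... Unused.
#' @return The per-height table of ChIP counts, mean background counts
#'   and empirical FDR.
#' @export
tidy.fdr_calibration <- function(x, ...) {
  x$table
}

#' Tidy a Venn overlap result
#'
#' @param x A `venn_result` from [intersect_sets()].
#' @param ... Unused.
#' @return A tibble of class counts.
#' @export
tidy.venn_result <- function(x, ...) {
  tibble(
    class = c("both", "a_only", "b_only", "a_shared", "b_shared"),
    n = c(x$both, x$a_only, x$b_only, x$a_shared, x$b_shared)
  )
}

#' Tidy a repeat-fraction result
#'
#' @param x A `repeat_fraction` from [repeat_fraction_histogram()].
#' @param ... Unused.
#' @return The decile histogram tibble.
#' @export
tidy.repeat_fraction <- function(x, ...) {
  x$histogram
}
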