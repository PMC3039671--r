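# Input-driven background model: copy-number events and over-sequenced
# artifact regions are detected from the (smoothed) input channel, then the
# ChIP track is corrected to look like a single-copy, bias-free genome.

#' Estimate the genome-average input depth
#'
#' The "average coverage" baseline against which duplications and
#' deletions are judged: a trimmed mean of the non-zero bins, so
#' amplified hotspots and collapsed repeats do not drag the baseline.
#'
#' @param input_track A `coverage_track` built from the input channel.
#' @param trim Fraction trimmed from each tail (default 0.01).
#' @return The baseline depth (a single number).
#' @export
estimate_global_mean <- function(input_track, trim = 0.01) {
  stopifnot(inherits(input_track, "coverage_track"))
  v <- unlist(input_track$depth, use.names = FALSE)
  v <- v[v > 0]
  if (length(v) == 0) {
    abort("input track is all zero: no baseline coverage to normalize against")
  }
  mean(v, trim = trim)
}

segment_tbl <- function(chrom = character(), start = integer(), end = integer(),
                        copy_number = numeric(), klass = character()) {
  tibble(chrom = chrom, start = start, end = end,
         copy_number = copy_number, klass = klass)
}

#' Detect duplication and deletion segments from input coverage
#'
#' Maximal runs of bins whose (smoothed) input depth is at least
#' `dup_fold` times the baseline are called duplications; runs at or
#' below `del_fold` times the baseline are deletions.  Runs shorter than
#' `min_len` bp are ignored.  Copy number is the run's mean depth over
#' the baseline, quantized to halves (2 copies = depth 2x baseline on a
#' diploid-normal scale of 1): fractional estimates at realistic depth
#' are too noisy to divide by directly.
#'
#' @param input_track A `coverage_track` of the input channel, ideally
#'   smoothed first with [sliding_average()].
#' @param baseline Genome-average depth from [estimate_global_mean()].
#' @param dup_fold,del_fold Fold thresholds (defaults 1.5 and 0.5).
#' @param min_len Minimum event length in bp (default 2000).
#' @return A tibble of segments (`chrom`, `start`, `end`, `copy_number`,
#'   `klass`), non-overlapping and sorted; bins in no segment are
#'   implicitly normal.
#' @export
detect_copy_number <- function(input_track, baseline, dup_fold = 1.5,
                               del_fold = 0.5, min_len = 2000) {
  stopifnot(inherits(input_track, "coverage_track"))
  if (baseline <= 0) abort("`baseline` must be positive")
  if (!(dup_fold > 1 && del_fold < 1 && del_fold > 0)) {
    abort("need dup_fold > 1 > del_fold > 0")
  }
  bs <- input_track$bin_size
  out <- lapply(names(input_track$depth), function(ch) {
    v <- input_track$depth[[ch]]
    state <- integer(length(v))
    state[v >= dup_fold * baseline] <- 1L
    state[v <= del_fold * baseline] <- -1L
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != 0L & r$lengths * bs >= min_len
    if (!any(keep)) return(NULL)
    i <- which(keep)
    ratio <- vapply(i, function(j) {
      mean(v[starts[j]:ends[j]]) / baseline
    }, numeric(1))
    cn <- ifelse(r$values[i] == 1L,
                 pmax(1.5, round_half_up(ratio * 2) / 2),
                 pmax(0.25, round_half_up(ratio * 2) / 2))
    segment_tbl(
      chrom = rep(ch, length(i)),
      start = as.integer((starts[i] - 1) * bs),
      end = as.integer(pmin(ends[i] * bs, input_track$chrom_sizes[[ch]])),
      copy_number = cn,
      klass = ifelse(r$values[i] == 1L, "duplication", "deletion")
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) segment_tbl() else dplyr::arrange(res, .data$chrom, .data$start)
}

#' Detect over-sequenced artifact regions
#'
#' Library and mapping artifacts produce focal regions whose input
#' coverage is higher than chance allows yet corresponds to no plausible
#' copy number.  A one-sample t-statistic of each sliding window of bins
#' against the global mean is computed; windows significant at `alpha`
#' after Bonferroni correction over all windows are flagged and merged.
#' Merged regions whose fold over baseline could still be explained by a
#' genuine amplification (fold between `dup_fold` and `max_copy_fold`)
#' are left to [detect_copy_number()]; the rest are returned as
#' `oversequenced` segments (copy number recorded as the observed fold).
#'
#' @param input_track A `coverage_track` of the input channel.
#' @param window Window length in bins (default 10; must be >= 2).
#' @param alpha Family-wise significance level (default 0.01).
#' @param baseline Depth baseline from [estimate_global_mean()]; when
#'   `NULL` it is recomputed from the track.
#' @param dup_fold Lower fold bound of the genuine-duplication band
#'   (default 1.5).
#' @param max_copy_fold Largest fold attributable to a real copy-number
#'   event (default 5); flagged regions above it are always artifacts.
#' @return A tibble of `oversequenced` segments.
#' @export
detect_oversequenced <- function(input_track, window = 10, alpha = 0.01,
                                 baseline = NULL, dup_fold = 1.5,
                                 max_copy_fold = 5) {
  stopifnot(inherits(input_track, "coverage_track"))
  if (window < 2) abort("`window` must be >= 2 bins")
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1)")
  if (is.null(baseline)) baseline <- estimate_global_mean(input_track)
  mu <- mean(unlist(input_track$depth, use.names = FALSE))
  bs <- input_track$bin_size
  n_windows <- sum(vapply(input_track$depth, function(v) {
    max(0L, length(v) - as.integer(window) + 1L)
  }, integer(1)))
  if (n_windows == 0) {
    warn("every chromosome is shorter than `window`; nothing tested")
    return(segment_tbl())
  }
  out <- lapply(names(input_track$depth), function(ch) {
    v <- input_track$depth[[ch]]
    n <- length(v)
    if (n < window) {
      warn(sprintf("%s: fewer bins (%d) than window (%d); skipped", ch, n, window))
      return(NULL)
    }
    k <- n - window + 1
    cs <- cumsum(c(0, v))
    cs2 <- cumsum(c(0, v^2))
    i <- seq_len(k)
    m <- (cs[i + window] - cs[i]) / window
    ss <- (cs2[i + window] - cs2[i]) - window * m^2
    s <- sqrt(pmax(ss, 0) / (window - 1))
    t_stat <- (m - mu) / (s / sqrt(window))
    t_stat[s == 0 & m > mu] <- Inf
    t_stat[s == 0 & m <= mu] <- -Inf
    p <- pt(t_stat, df = window - 1, lower.tail = FALSE)
    flagged <- p * n_windows < alpha
    if (!any(flagged)) return(NULL)
    # Union of flagged windows -> merged bin spans.
    covered <- logical(n)
    for (j in which(flagged)) covered[j:(j + window - 1)] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    idx <- which(r$values)
    fold <- vapply(idx, function(j) mean(v[starts[j]:ends[j]]) / baseline,
                   numeric(1))
    keep <- fold > max_copy_fold | fold < dup_fold
    if (!any(keep)) return(NULL)
    idx <- idx[keep]
    segment_tbl(
      chrom = rep(ch, length(idx)),
      start = as.integer((starts[idx] - 1) * bs),
      end = as.integer(pmin(ends[idx] * bs, input_track$chrom_sizes[[ch]])),
      copy_number = fold[keep],
      klass = rep("oversequenced", length(idx))
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) segment_tbl() else dplyr::arrange(res, .data$chrom, .data$start)
}

#' Normalize a ChIP track to a single-copy, bias-free genome
#'
#' Bins inside duplication or deletion segments are divided by the
#' segment copy number (a multiplicative model: twice the template
#' yields twice the signal); bins inside over-sequenced segments have no
#' meaningful copy number and are masked to the global ChIP median.
#' Bins outside every segment are untouched.
#'
#' @param chip_track A `coverage_track` of the ChIP channel, on the same
#'   bin grid as the segments were called on.
#' @param segments Segment tibble from [detect_copy_number()] /
#'   [detect_oversequenced()] (may be row-bound); must not overlap.
#' @return The corrected `coverage_track`, flagged `normalized`.
#' @export
normalize_chip <- function(chip_track, segments) {
  stopifnot(inherits(chip_track, "coverage_track"))
  if (chip_track$normalized) {
    warn("track is already normalized; dividing again")
  }
  if (nrow(segments) > 0) {
    sg <- dplyr::arrange(segments, .data$chrom, .data$start)
    same <- sg$chrom[-1] == sg$chrom[-nrow(sg)]
    if (any(same & sg$start[-1] < sg$end[-nrow(sg)])) {
      abort("segments overlap; copy-number and artifact calls must be disjoint")
    }
  }
  bs <- chip_track$bin_size
  chip_median <- median(unlist(chip_track$depth, use.names = FALSE))
  depth <- chip_track$depth
  for (i in seq_len(nrow(segments))) {
    ch <- segments$chrom[i]
    if (is.null(depth[[ch]])) next
    b0 <- floor(segments$start[i] / bs) + 1
    b1 <- min(ceiling(segments$end[i] / bs), length(depth[[ch]]))
    if (b0 > b1) next
    if (segments$klass[i] == "oversequenced") {
      depth[[ch]][b0:b1] <- chip_median
    } else {
      depth[[ch]][b0:b1] <- depth[[ch]][b0:b1] / segments$copy_number[i]
    }
  }
  new_coverage_track(depth, bs, chip_track$extension, chip_track$chrom_sizes,
                     normalized = TRUE, smoothed = chip_track$smoothed)
}

#' Export background segments as BED6
#'
#' Name field carries the segment class, score the copy number times
#' 100.
#'
#' @param segments Segment tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segment_bed <- function(segments, path) {
  if (nrow(segments) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", segments$chrom,
                     as.integer(segments$start), as.integer(segments$end),
                     segments$klass, as.integer(round(segments$copy_number * 100))),
             path)
  invisible(path)
}
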