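# The peak caller: shuffle-based FDR calibration of a height cutoff, then
# extraction of enriched regions above it.  Narrow mode reproduces classic
# punctate transcription-factor calling; broad mode smooths the track and
# merges across small gaps so spreading histone marks come out as contiguous
# binding regions.

#' Peak-calling configuration
#'
#' Bundles every tunable of [call_peaks()].  Mode-dependent defaults:
#' broad mode uses 200 bp bins, a 9-bin smoothing window, a 1 kb merge
#' gap and a 400 bp minimum region; narrow mode uses 50 bp bins, no
#' smoothing, a 100 bp merge gap and a 100 bp minimum region.
#'
#' @param mode `"broad"` (spreading histone marks) or `"narrow"`
#'   (punctate binding).
#' @param fdr Target false-discovery fraction in (0, 1]: the tolerated
#'   ratio of background regions to ChIP regions at the chosen cutoff.
#' @param bin_size Coverage bin width in bp.
#' @param extension Fragment extension in bp (default 350).
#' @param smoothing_window ChIP smoothing window in bins (odd; 1 = no
#'   smoothing).
#' @param input_smoothing_window Smoothing window for the input channel
#'   before copy-number detection (default 9 bins).
#' @param merge_gap Regions separated by at most this many bp of
#'   sub-threshold signal are merged.
#' @param min_region_len Regions shorter than this are discarded.
#' @param seed Integer seed fixing the background shuffles.
#' @param n_background_draws Number of shuffled backgrounds averaged in
#'   the FDR estimate (default 3).
#' @param n_background_bins Number of equal-width sampling bins the
#'   genome is split into for the shuffle; `NULL` means one per megabase
#'   (at least one per chromosome), which preserves megabase-scale
#'   sequencing bias while destroying local structure.
#' @param dup_fold,del_fold,min_cn_len Copy-number detection thresholds,
#'   see [detect_copy_number()].
#' @param oversequenced_window,oversequenced_alpha,max_copy_fold
#'   Artifact detection parameters, see [detect_oversequenced()].
#' @return A `peak_call_config` list.
#' @export
peak_call_config <- function(mode = c("broad", "narrow"), fdr = 0.01,
                             bin_size = NULL, extension = 350,
                             smoothing_window = NULL,
                             input_smoothing_window = 9,
                             merge_gap = NULL, min_region_len = NULL,
                             seed = 1L, n_background_draws = 3L,
                             n_background_bins = NULL,
                             dup_fold = 1.5, del_fold = 0.5, min_cn_len = 2000,
                             oversequenced_window = 10,
                             oversequenced_alpha = 0.01, max_copy_fold = 5) {
  mode <- match.arg(mode)
  broad <- mode == "broad"
  cfg <- list(
    mode = mode,
    fdr = fdr,
    bin_size = as.integer(bin_size %||% if (broad) 200L else 50L),
    extension = as.integer(extension),
    smoothing_window = as.integer(smoothing_window %||% if (broad) 9L else 1L),
    input_smoothing_window = as.integer(input_smoothing_window),
    merge_gap = as.integer(merge_gap %||% if (broad) 1000L else 100L),
    min_region_len = as.integer(min_region_len %||% if (broad) 400L else 100L),
    seed = as.integer(seed),
    n_background_draws = as.integer(n_background_draws),
    n_background_bins = n_background_bins,
    dup_fold = dup_fold, del_fold = del_fold, min_cn_len = min_cn_len,
    oversequenced_window = oversequenced_window,
    oversequenced_alpha = oversequenced_alpha, max_copy_fold = max_copy_fold
  )
  if (!(cfg$fdr > 0 && cfg$fdr <= 1)) abort("`fdr` must be in (0, 1]")
  if (cfg$merge_gap < 0) abort("`merge_gap` must be >= 0")
  if (cfg$n_background_draws < 1) abort("`n_background_draws` must be >= 1")
  if (cfg$smoothing_window %% 2 == 0) abort("`smoothing_window` must be odd")
  structure(cfg, class = "peak_call_config")
}

#' Shuffle input tags within coarse sampling bins
#'
#' Builds the null tag set used for FDR calibration: the genome is
#' partitioned into `n_bins` equal-width sampling bins (spread over
#' chromosomes in proportion to length, at least one each) and every
#' input tag is re-placed uniformly at random within its bin.  Per-bin
#' tag counts and strands are conserved exactly, so megabase-scale
#' sequencing bias survives the shuffle while any real local enrichment
#' is destroyed.
#'
#' @param input_tags Tag tibble of the input channel.
#' @param n_bins Total number of sampling bins across the genome.
#' @param chrom_sizes Named chromosome lengths in bp.
#' @param seed Integer seed; the same seed reproduces the same shuffle.
#' @return A tag tibble of identical size, sorted by chromosome and
#'   position.
#' @export
make_background <- function(input_tags, n_bins, chrom_sizes, seed = 1L) {
  stopifnot(is.data.frame(input_tags))
  if (nrow(input_tags) == 0) abort("input tag set is empty")
  if (n_bins < 1) abort("`n_bins` must be >= 1")
  total <- sum(chrom_sizes)
  per_chrom <- pmax(round(n_bins * chrom_sizes / total), 1L)
  widths <- chrom_sizes / per_chrom
  if (any(widths < 1)) {
    abort("`n_bins` exceeds the bp resolution of the genome")
  }
  rl <- tag_read_length(input_tags)
  out <- withr::with_seed(seed, {
    pieces <- lapply(names(chrom_sizes), function(ch) {
      sel <- input_tags$chrom == ch
      if (!any(sel)) return(NULL)
      pos <- input_tags$pos[sel]
      w <- widths[[ch]]
      bin <- pmin(floor(pos / w), per_chrom[[ch]] - 1)
      lo <- bin * w
      hi <- pmin(lo + w, chrom_sizes[[ch]])
      new_pos <- as.integer(floor(lo + runif(length(pos)) * (hi - lo)))
      tibble(chrom = ch, pos = pmin(new_pos, as.integer(chrom_sizes[[ch]]) - 1L),
             strand = input_tags$strand[sel])
    })
    dplyr::bind_rows(pieces)
  })
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  attr(out, "read_length") <- rl
  out
}

# Default sampling-bin count: one per megabase, at least one per chromosome.
default_background_bins <- function(chrom_sizes) {
  max(length(chrom_sizes), round(sum(chrom_sizes) / 1e6))
}

#' Extract regions above a height cutoff
#'
#' Maximal runs of bins at or above `height`; runs separated by at most
#' `merge_gap` bp of sub-threshold bins are merged (jagged enrichment
#' profiles dip below any single cutoff many times across one biological
#' domain), and merged spans shorter than `min_region_len` bp are
#' discarded.  Height statistics are computed over the full merged span,
#' including the bridged gaps.
#'
#' @param track A `coverage_track`.
#' @param height Depth cutoff (> 0).
#' @param merge_gap Maximum bridged gap in bp (default 0).
#' @param min_region_len Minimum region length in bp (default 0).
#' @return A tibble of regions: `chrom`, `start`, `end`, `max_height`,
#'   `area` (depth x bp) and `mean_height`; empty when nothing
#'   qualifies.
#' @export
regions_above <- function(track, height, merge_gap = 0, min_region_len = 0) {
  stopifnot(inherits(track, "coverage_track"))
  if (height <= 0) abort("`height` must be positive")
  bs <- track$bin_size
  gap_bins <- floor(merge_gap / bs)
  out <- lapply(names(track$depth), function(ch) {
    v <- track$depth[[ch]]
    r <- rle(v >= height)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    i <- which(r$values)
    if (length(i) == 0) return(NULL)
    run_start <- starts[i]
    run_end <- ends[i]
    if (length(i) > 1) {
      gap <- run_start[-1] - run_end[-length(i)] - 1
      grp <- cumsum(c(1, as.integer(gap > gap_bins)))
      first <- !duplicated(grp)
      last <- rev(!duplicated(rev(grp)))
      run_start <- run_start[first]
      run_end <- run_end[last]
    }
    span_end <- pmin(run_end * bs, track$chrom_sizes[[ch]])
    span_start <- (run_start - 1) * bs
    keep <- (span_end - span_start) >= min_region_len
    if (!any(keep)) return(NULL)
    ks <- which(keep)
    stats <- vapply(ks, function(j) {
      b <- v[run_start[j]:run_end[j]]
      c(max(b), sum(b) * bs, mean(b))
    }, numeric(3))
    tibble(chrom = ch,
           start = as.integer(span_start[ks]),
           end = as.integer(span_end[ks]),
           max_height = stats[1, ],
           area = stats[2, ],
           mean_height = stats[3, ])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    tibble(chrom = character(), start = integer(), end = integer(),
           max_height = numeric(), area = numeric(), mean_height = numeric())
  } else {
    res
  }
}

#' Calibrate the height cutoff at a target FDR
#'
#' Builds `n_background_draws` shuffled backgrounds from the input tags
#' (see [make_background()]), turns each into a coverage track matching
#' the ChIP processing (same bins, extension and - in broad mode -
#' smoothing), then walks candidate cutoffs upward in steps of the
#' track's depth quantum.  At each height the empirical FDR is the mean
#' background region count over the ChIP region count; the first height
#' at which it drops to the target is returned.  If the ChIP region
#' count reaches zero first, no cutoff attains the target and
#' calibration fails.
#'
#' @param chip_track The processed (normalized, optionally smoothed)
#'   ChIP `coverage_track`.
#' @param input_tags Input-channel tag tibble.
#' @param config A [peak_call_config()].
#' @param segments Optional background segments (from
#'   [detect_copy_number()] / [detect_oversequenced()]) applied to each
#'   shuffled background track, so the null model carries the same
#'   copy-number correction as the ChIP track it calibrates.
#' @return An `fdr_calibration` object: the chosen `height_cutoff` plus
#'   the per-height table of ChIP counts, mean background counts and
#'   empirical FDR.
#' @export
calibrate_height_cutoff <- function(chip_track, input_tags, config,
                                    segments = NULL) {
  stopifnot(inherits(chip_track, "coverage_track"),
            inherits(config, "peak_call_config"))
  chrom_sizes <- chip_track$chrom_sizes
  n_bins <- config$n_background_bins %||% default_background_bins(chrom_sizes)
  bg_tracks <- lapply(seq_len(config$n_background_draws), function(d) {
    bg <- make_background(input_tags, n_bins, chrom_sizes,
                          seed = config$seed + d)
    tr <- build_coverage(bg, config$bin_size, config$extension, chrom_sizes)
    if (!is.null(segments) && nrow(segments) > 0) {
      tr <- suppressWarnings(normalize_chip(tr, segments))
    }
    if (config$smoothing_window > 1) {
      tr <- sliding_average(tr, config$smoothing_window)
    }
    tr
  })
  step <- depth_quantum(chip_track)
  max_h <- max(unlist(chip_track$depth, use.names = FALSE))
  # Candidate cutoffs start at the background tracks' mean depth: below the
  # genome-wide null expectation the count ratio compares the fragmentation of
  # noise, not enrichment, and is meaningless.
  bg_mean <- mean(unlist(lapply(bg_tracks, function(tr) {
    unlist(tr$depth, use.names = FALSE)
  })))
  rows <- list()
  h <- max(step, ceiling(bg_mean / step) * step)
  cutoff <- NA_real_
  while (h <= max_h + step / 2) {
    chip_n <- nrow(regions_above(chip_track, h, config$merge_gap,
                                 config$min_region_len))
    bg_n <- mean(vapply(bg_tracks, function(tr) {
      nrow(regions_above(tr, h, config$merge_gap, config$min_region_len))
    }, numeric(1)))
    # A permutation-style background estimate should never be exactly zero:
    # observing no background region in d draws bounds the rate, it does not
    # abolish it.  Floor the estimate at half a count across the draws, so a
    # lone ChIP region just above the background maxima is not accepted on a
    # spuriously zero FDR.
    bg_eff <- if (bg_n > 0) bg_n else 0.5 / config$n_background_draws
    fdr_h <- bg_eff / max(chip_n, 1)
    rows[[length(rows) + 1]] <- tibble(height = h, chip_count = chip_n,
                                       background_count = bg_n,
                                       empirical_fdr = fdr_h)
    if (chip_n == 0) break
    if (fdr_h <= config$fdr) {
      cutoff <- h
      break
    }
    h <- h + step
  }
  tab <- dplyr::bind_rows(rows)
  if (is.na(cutoff)) {
    abort(paste0(
      "FDR calibration failed: the ChIP region count reached zero before the ",
      sprintf("empirical FDR dropped to %g. ", config$fdr),
      "There is no significant enrichment at this stringency; consider a ",
      "higher `fdr`."
    ))
  }
  structure(list(height_cutoff = cutoff, table = tab, target_fdr = config$fdr,
                 step = step, n_background_draws = config$n_background_draws),
            class = "fdr_calibration")
}

#' @export
print.fdr_calibration <- function(x, ...) {
  at <- x$table[x$table$height == x$height_cutoff, ]
  cat(sprintf(
    "<fdr_calibration> cutoff %.3g (target FDR %g, step %.3g, %d background draw(s))\n",
    x$height_cutoff, x$target_fdr, x$step, x$n_background_draws))
  cat(sprintf("  at cutoff: %d ChIP regions vs %.2f mean background regions (FDR %.3g)\n",
              as.integer(at$chip_count), at$background_count, at$empirical_fdr))
  invisible(x)
}

#' Call enriched regions from ChIP and input tag sets
#'
#' The full pipeline: build the input coverage track, smooth it,
#' estimate the genome-average baseline, detect copy-number events and
#' over-sequenced artifacts, build and normalize the ChIP track, smooth
#' it in broad mode, calibrate the height cutoff at the target FDR by
#' binned shuffling of the input tags, and extract the regions above the
#' cutoff.  Deterministic given `config$seed`.
#'
#' @param chip_tags,input_tags Tag tibbles for the ChIP and input
#'   channels (e.g. from [read_tag_bed()]).
#' @param config A [peak_call_config()].
#' @param chrom_sizes Named chromosome lengths; inferred from the tags
#'   when `NULL`.
#' @return A `peak_call` object with elements `peaks` (tibble of
#'   regions with `name`, `max_height`, `area`, `mean_height`, `mode`),
#'   `calibration` (the [calibrate_height_cutoff()] result), `segments`
#'   (background segments applied during normalization) and `config`.
#'   Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' sim <- simulate_experiment(sim_config(
#'   chrom_sizes = c(chrA = 4e5),
#'   planted_regions = tibble::tibble(chrom = "chrA", start = 1e5, end = 1.3e5,
#'                                    fold = 8, profile = "block"),
#'   n_chip_tags = 2e4, n_input_tags = 2e4, seed = 11
#' ))
#' res <- call_peaks(sim$chip, sim$input,
#'                   peak_call_config(mode = "broad", fdr = 0.05, seed = 11),
#'                   chrom_sizes = c(chrA = 4e5))
#' tidy(res)
#' @export
call_peaks <- function(chip_tags, input_tags, config = peak_call_config(),
                       chrom_sizes = NULL) {
  stopifnot(inherits(config, "peak_call_config"))
  if (nrow(chip_tags) == 0 || nrow(input_tags) == 0) {
    abort("both ChIP and input tag sets must be non-empty")
  }
  if (is.null(chrom_sizes)) {
    both <- dplyr::bind_rows(chip_tags[c("chrom", "pos")],
                             input_tags[c("chrom", "pos")])
    chrom_sizes <- infer_chrom_sizes(both, config$extension)
  }
  input_track <- build_coverage(input_tags, config$bin_size, config$extension,
                                chrom_sizes)
  input_smooth <- if (config$input_smoothing_window > 1) {
    sliding_average(input_track, config$input_smoothing_window)
  } else {
    input_track
  }
  baseline <- estimate_global_mean(input_smooth)
  cn <- detect_copy_number(input_smooth, baseline, config$dup_fold,
                           config$del_fold, config$min_cn_len)
  # Artifact detection needs approximately independent bins: smoothing (or
  # bins much narrower than a fragment) makes neighbouring bins nearly equal,
  # collapsing the within-window variance and inflating the t-statistic.  Use
  # an unsmoothed track with bins at least one fragment wide.
  artifact_bin <- max(config$bin_size,
                      ceiling(config$extension / config$bin_size) * config$bin_size)
  artifact_track <- if (artifact_bin == config$bin_size) {
    input_track
  } else {
    build_coverage(input_tags, artifact_bin, config$extension, chrom_sizes)
  }
  overseq <- detect_oversequenced(artifact_track, config$oversequenced_window,
                                  config$oversequenced_alpha,
                                  estimate_global_mean(artifact_track),
                                  config$dup_fold, config$max_copy_fold)
  # An artifact region wins over any copy-number call it overlaps.
  if (nrow(cn) > 0 && nrow(overseq) > 0) {
    hits <- GenomicRanges::countOverlaps(as_granges(cn), as_granges(overseq))
    cn <- cn[hits == 0, ]
  }
  segments <- dplyr::bind_rows(cn, overseq)
  chip_track <- build_coverage(chip_tags, config$bin_size, config$extension,
                               chrom_sizes)
  chip_track <- normalize_chip(chip_track, segments)
  if (config$smoothing_window > 1) {
    chip_track <- sliding_average(chip_track, config$smoothing_window)
  }
  calibration <- calibrate_height_cutoff(chip_track, input_tags, config,
                                         segments = segments)
  peaks <- regions_above(chip_track, calibration$height_cutoff,
                         config$merge_gap, config$min_region_len)
  peaks <- dplyr::arrange(peaks, .data$chrom, .data$start)
  if (nrow(peaks) > 0) {
    peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
    peaks$mode <- config$mode
    peaks <- peaks[c("chrom", "start", "end", "name", "max_height", "area",
                     "mean_height", "mode")]
  } else {
    peaks <- tibble(chrom = character(), start = integer(), end = integer(),
                    name = character(), max_height = numeric(),
                    area = numeric(), mean_height = numeric(),
                    mode = character())
  }
  structure(list(peaks = peaks, calibration = calibration, segments = segments,
                 config = config, chrom_sizes = chrom_sizes,
                 chip_track = chip_track),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("<peak_call> %s mode: %d region(s), %s bp covered\n",
              x$config$mode, nrow(x$peaks),
              format(sum(x$peaks$end - x$peaks$start), big.mark = ",")))
  cat(sprintf("  height cutoff %.3g at target FDR %g; %d background segment(s) applied\n",
              x$calibration$height_cutoff, x$config$fdr, nrow(x$segments)))
  invisible(x)
}
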