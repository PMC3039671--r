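# Binned, fragment-extended coverage tracks.
#
# A coverage_track holds one depth vector per chromosome at a fixed bin size.
# Depth is the MEAN per-bp fragment pileup within the bin (not a tag count),
# so changing the bin size rescales values smoothly and the invariant
# sum(depth) * bin_size ~= n_tags * extension holds up to chromosome-end
# truncation.

new_coverage_track <- function(depth, bin_size, extension, chrom_sizes,
                               normalized = FALSE, smoothed = FALSE) {
  structure(
    list(depth = depth, bin_size = bin_size, extension = extension,
         chrom_sizes = chrom_sizes, normalized = normalized, smoothed = smoothed),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %d chromosome(s), bin %d bp, extension %d bp%s%s\n",
    length(x$depth), x$bin_size, x$extension,
    if (x$normalized) ", normalized" else "",
    if (x$smoothed) ", smoothed" else ""
  ))
  for (ch in names(x$depth)) {
    v <- x$depth[[ch]]
    cat(sprintf("  %s: %d bins, mean depth %.2f, max %.2f\n",
                ch, length(v), mean(v), max(v)))
  }
  invisible(x)
}

#' Flatten a coverage track to a tibble
#'
#' One row per bin with half-open bin coordinates, suitable for plotting
#' or bedGraph export.
#'
#' @param x A `coverage_track`.
#' @param ... Unused.
#' @return A tibble with columns `chrom`, `start`, `end`, `depth`.
#' @export
as_tibble.coverage_track <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$depth), function(ch) {
    v <- x$depth[[ch]]
    start <- (seq_along(v) - 1) * x$bin_size
    tibble(chrom = ch, start = start,
           end = pmin(start + x$bin_size, x$chrom_sizes[[ch]]),
           depth = v)
  }))
}

#' Export a coverage track as bedGraph
#'
#' @param track A `coverage_track`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  tb <- as_tibble(track)
  writeLines(sprintf("%s\t%d\t%d\t%g", tb$chrom, as.integer(tb$start),
                     as.integer(tb$end), tb$depth), path)
  invisible(path)
}

#' Build a binned coverage track from mapped tags
#'
#' Each tag is extended to the average sonicated fragment length in its
#' read direction: a `+` strand tag at 5' position `p` contributes the
#' fragment `[p, p + extension)`, a `-` strand tag the mirror-image
#' fragment ending at its 5' position.  The per-bp fragment pileup is
#' then averaged within fixed-width bins.
#'
#' @param tags A tag tibble (`chrom`, `pos`, `strand`), e.g. from
#'   [read_tag_bed()] or [simulate_experiment()].
#' @param bin_size Bin width in bp (default 200, suited to broad marks;
#'   use ~50 for narrow peak calling).
#' @param extension Fragment extension in bp; defaults to 350, the
#'   midpoint of a typical 300-500 bp sonication size range.  Must be at
#'   least the mapped read length.
#' @param chrom_sizes Named vector of chromosome lengths in bp.  When
#'   `NULL`, each chromosome extends to its last tag plus one fragment.
#' @return A `coverage_track`.
#' @examples
#' tags <- tibble::tibble(chrom = "chr1", pos = 0L, strand = "+")
#' build_coverage(tags, bin_size = 100, extension = 200,
#'                chrom_sizes = c(chr1 = 1000))
#' @export
build_coverage <- function(tags, bin_size = 200, extension = 350,
                           chrom_sizes = NULL) {
  stopifnot(is.data.frame(tags), bin_size >= 1)
  rl <- tag_read_length(tags)
  if (extension < rl) {
    abort(sprintf("extension (%d bp) must be >= read length (%d bp)",
                  as.integer(extension), rl))
  }
  if (is.null(chrom_sizes)) {
    if (nrow(tags) == 0) {
      abort("cannot infer chromosome sizes from an empty tag set; pass `chrom_sizes`")
    }
    chrom_sizes <- infer_chrom_sizes(tags, extension)
  }
  bin_size <- as.integer(bin_size)
  extension <- as.integer(extension)
  depth <- lapply(names(chrom_sizes), function(ch) {
    L <- as.integer(chrom_sizes[[ch]])
    nb <- ceiling(L / bin_size)
    sel <- tags$chrom == ch
    if (!any(sel)) {
      return(numeric(nb))
    }
    pos <- tags$pos[sel]
    plus <- tags$strand[sel] == "+"
    s <- ifelse(plus, pos, pos - extension + 1L)
    e <- s + extension
    s <- pmax(s, 0L)
    e <- pmin(e, L)
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    # Per-bp pileup via difference array + cumulative sum.
    delta <- tabulate(s + 1L, nbins = L + 1L) - tabulate(e + 1L, nbins = L + 1L)
    per_bp <- cumsum(delta)[seq_len(L)]
    pad <- nb * bin_size - L
    if (pad > 0) per_bp <- c(per_bp, rep(NA_real_, pad))
    m <- matrix(per_bp, nrow = bin_size)
    colMeans(m, na.rm = TRUE)
  })
  names(depth) <- names(chrom_sizes)
  new_coverage_track(depth, bin_size, extension, chrom_sizes)
}

#' Smooth a coverage track with a sliding average
#'
#' Replaces each bin by the mean of the `window` bins centred on it, so
#' that the jagged "mountain range" profiles typical of spreading
#' histone marks rise above a single cutoff as one contiguous run rather
#' than many fragments.  At chromosome ends the window shrinks to the
#' available bins, so constant tracks stay constant; total area is not
#' exactly conserved at the edges.
#'
#' @param track A `coverage_track`.
#' @param window Odd number of bins; `window = 1` returns the input
#'   unchanged.
#' @return A smoothed `coverage_track` (flagged `smoothed`).
#' @export
sliding_average <- function(track, window) {
  stopifnot(inherits(track, "coverage_track"))
  if (length(window) != 1 || window < 1 || window %% 2 == 0) {
    abort("`window` must be a positive odd number of bins")
  }
  if (window == 1) {
    return(track)
  }
  w <- (window - 1) / 2
  depth <- lapply(track$depth, function(x) {
    n <- length(x)
    if (n == 0) return(x)
    cs <- cumsum(c(0, x))
    i <- seq_len(n)
    lo <- pmax(i - w, 1)
    hi <- pmin(i + w, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  })
  new_coverage_track(depth, track$bin_size, track$extension, track$chrom_sizes,
                     normalized = track$normalized, smoothed = TRUE)
}

# Smallest meaningful height increment for a track: one fragment of depth for a
# raw pileup; for smoothed tracks the smallest positive difference between
# distinct observed values, floored at 0.25.
depth_quantum <- function(track) {
  if (!track$smoothed) {
    return(1)
  }
  v <- sort(unique(round(unlist(track$depth, use.names = FALSE), 9)))
  d <- diff(v)
  d <- d[d > 1e-9]
  if (length(d) == 0) {
    return(1)
  }
  max(0.25, min(d))
}
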