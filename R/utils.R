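# Internal helpers shared across modules.

# Validate a tibble of half-open intervals (chrom, start, end).
check_intervals <- function(x, arg = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals", arg))
  }
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg, paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
      abort(sprintf("`%s` has non-finite coordinates", arg))
    }
    if (any(x$start < 0) || any(x$start >= x$end)) {
      abort(sprintf("`%s` violates 0 <= start < end", arg))
    }
  }
  invisible(x)
}

# Tibble of half-open intervals -> GRanges (1-based closed internally).
as_granges <- function(x) {
  if (nrow(x) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# GRanges -> tibble of half-open intervals.
granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Gap in bp between two half-open intervals on the same chromosome (0 if they touch
# or overlap).
interval_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmax(b_start - a_end, a_start - b_end))
}

tag_read_length <- function(tags) {
  rl <- attr(tags, "read_length", exact = TRUE)
  if (is.null(rl)) 0L else as.integer(rl)
}

# Per-chromosome sizes inferred from tags when the caller has no assembly table:
# the largest 5' position plus one fragment.
infer_chrom_sizes <- function(tags, extension) {
  stopifnot(nrow(tags) > 0)
  sz <- tapply(tags$pos, tags$chrom, max)
  setNames(as.numeric(sz) + extension, names(sz))
}

# Round half-up to `digits` decimals (base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
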