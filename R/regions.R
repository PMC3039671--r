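# Downstream analytics over called regions: dual-mark overlap, per-kb
# densities, genomic location classes, nearest genes, repeat content,
# finger-domain association and summary statistics.

#' Venn-style overlap between two region sets
#'
#' A region of set A is "shared" when it overlaps at least one region of
#' B by `min_overlap` bp, and symmetrically for B.  The `both` count is
#' the number of merged A-and-B overlap events, so one A region touching
#' two adjacent B regions contributes a single shared site; the per-set
#' shared-region counts are reported alongside because the two
#' accountings differ whenever regions of one set straddle several of
#' the other.
#'
#' @param a,b Tibbles of half-open intervals.
#' @param min_overlap Minimum overlap in bp to count (default 1).
#' @return A `venn_result` with counts `both`, `a_only`, `b_only`,
#'   `a_shared`, `b_shared` and the interval tibbles for each class.
#' @export
intersect_sets <- function(a, b, min_overlap = 1) {
  check_intervals(a)
  check_intervals(b)
  if (min_overlap < 1) abort("`min_overlap` must be >= 1 bp")
  gra <- as_granges(a)
  grb <- as_granges(b)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gra, grb, minoverlap = min_overlap))
  a_hit <- unique(S4Vectors::queryHits(hits))
  b_hit <- unique(S4Vectors::subjectHits(hits))
  ov <- if (length(hits) > 0) {
    GenomicRanges::reduce(GenomicRanges::pintersect(
      gra[S4Vectors::queryHits(hits)], grb[S4Vectors::subjectHits(hits)]
    ))
  } else {
    GenomicRanges::GRanges()
  }
  structure(list(
    both = length(ov),
    a_only = nrow(a) - length(a_hit),
    b_only = nrow(b) - length(b_hit),
    a_shared = length(a_hit),
    b_shared = length(b_hit),
    intervals = list(
      a_only = a[setdiff(seq_len(nrow(a)), a_hit), , drop = FALSE],
      b_only = b[setdiff(seq_len(nrow(b)), b_hit), , drop = FALSE],
      both = granges_to_tbl(ov)
    )
  ), class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("<venn_result> both: %d overlap event(s); A only: %d; B only: %d\n",
              x$both, x$a_only, x$b_only))
  cat(sprintf("  shared regions: %d of A, %d of B\n", x$a_shared, x$b_shared))
  invisible(x)
}

#' Tag density per kilobase of region
#'
#' Counts tag 5' positions inside each region and normalizes for region
#' size, the same "per 1000 base pairs" normalization applied to CAGE,
#' RNA-seq and motif counts.
#'
#' @param tags Tag tibble (`chrom`, `pos`).
#' @param regions Tibble of half-open intervals (must be non-empty).
#' @return `regions` with added `n_tags` and `density` (tags per kb)
#'   columns; the aggregate density (total tags x 1000 / total bp) is
#'   attached as the `aggregate_density` attribute.
#' @export
tag_density_per_kb <- function(tags, regions) {
  check_intervals(regions)
  if (nrow(regions) == 0) abort("`regions` must be non-empty")
  pts <- GenomicRanges::GRanges(tags$chrom,
                                IRanges::IRanges(tags$pos + 1L, width = 1L))
  n <- suppressWarnings(GenomicRanges::countOverlaps(as_granges(regions), pts))
  out <- regions
  out$n_tags <- as.integer(n)
  out$density <- 1000 * n / (regions$end - regions$start)
  attr(out, "aggregate_density") <-
    1000 * sum(n) / sum(regions$end - regions$start)
  out
}

#' Classify regions as promoter, intragenic or intergenic
#'
#' A region overlapping any window of `promoter_halfwidth` bp around a
#' transcription start site is a promoter (promoter wins when a region
#' also lies in a gene body); otherwise a region overlapping any gene
#' span is intragenic; everything else is intergenic.
#'
#' @param regions Tibble of half-open intervals.
#' @param genes Gene tibble from [read_gene_table()].
#' @param promoter_halfwidth Half-width of the promoter window around
#'   the TSS in bp (default 500).
#' @return `regions` with an added `location` column.
#' @export
classify_location <- function(regions, genes, promoter_halfwidth = 500) {
  check_intervals(regions)
  if (promoter_halfwidth <= 0) abort("`promoter_halfwidth` must be > 0")
  gr <- as_granges(regions)
  prom <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(genes$tss - promoter_halfwidth, 0) + 1L,
                     end = genes$tss + promoter_halfwidth + 1L)
  )
  body <- as_granges(genes)
  in_prom <- suppressWarnings(GenomicRanges::countOverlaps(gr, prom)) > 0
  in_body <- suppressWarnings(GenomicRanges::countOverlaps(gr, body)) > 0
  out <- regions
  out$location <- ifelse(in_prom, "promoter",
                         ifelse(in_body, "intragenic", "intergenic"))
  out
}

#' Map each region to its nearest gene
#'
#' The nearest gene minimizes the bp gap between the region span and the
#' gene span (zero when they overlap); ties are broken by the smaller
#' gap to the TSS, then by lexicographic gene id.  Regions on a
#' chromosome with no annotated gene map to `"none"`.
#'
#' @param regions Tibble of half-open intervals.
#' @param genes Gene tibble from [read_gene_table()].
#' @return `regions` with added `gene_id` and `gene_distance` columns
#'   (`gene_distance` is `NA` for the `"none"` sentinel).
#' @export
nearest_gene <- function(regions, genes) {
  check_intervals(regions)
  out <- regions
  out$gene_id <- rep("none", nrow(regions))
  out$gene_distance <- rep(NA_real_, nrow(regions))
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(nrow(regions))) {
    gi <- by_chrom[[regions$chrom[i]]]
    if (is.null(gi)) next
    gap <- interval_gap(regions$start[i], regions$end[i],
                        genes$start[gi], genes$end[gi])
    tss_gap <- pmax(0, regions$start[i] - genes$tss[gi],
                    genes$tss[gi] - (regions$end[i] - 1))
    ord <- order(gap, tss_gap, genes$gene_id[gi])
    best <- gi[ord[1]]
    out$gene_id[i] <- genes$gene_id[best]
    out$gene_distance[i] <- gap[ord[1]]
  }
  out
}

#' Repeat content of each peak
#'
#' Repeat intervals are merged (union) first, so the result does not
#' depend on how fragmented the repeat annotation is; each peak's
#' percent-repetitive is then 100 x overlapping bp / peak length, and
#' peaks are binned into deciles `[0,10], (10,20], ..., (90,100]`.
#' When a comparison peak set is supplied, the ratio of top-decile
#' (91-100% repetitive) counts between the two sets is also reported.
#'
#' @param peaks Tibble of half-open intervals.
#' @param repeats Tibble of repeat intervals (possibly overlapping).
#' @param comparison_peaks Optional second peak set for the top-decile
#'   count ratio (`peaks` over `comparison_peaks`).
#' @return A `repeat_fraction` object: `per_peak` (peaks with
#'   `percent_repeat` and `decile`), `histogram` (counts per decile) and
#'   optionally `top_decile_ratio`.
#' @export
repeat_fraction_histogram <- function(peaks, repeats, comparison_peaks = NULL) {
  check_intervals(peaks)
  check_intervals(repeats)
  decile_levels <- c("[0,10]", paste0("(", seq(10, 90, 10), ",",
                                      seq(20, 100, 10), "]"))
  per_peak <- function(pk) {
    merged <- GenomicRanges::reduce(as_granges(repeats))
    gr <- as_granges(pk)
    ovbp <- rep(0, nrow(pk))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, merged))
    if (length(hits) > 0) {
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        gr[S4Vectors::queryHits(hits)], merged[S4Vectors::subjectHits(hits)]
      ))
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      ovbp[as.integer(names(agg))] <- as.numeric(agg)
    }
    out <- pk
    out$percent_repeat <- 100 * ovbp / (pk$end - pk$start)
    out$decile <- cut(out$percent_repeat, breaks = seq(0, 100, 10),
                      include.lowest = TRUE, labels = decile_levels)
    out
  }
  pp <- per_peak(peaks)
  hist <- dplyr::count(pp, .data$decile, .drop = FALSE, name = "n")
  res <- list(per_peak = pp, histogram = hist)
  if (!is.null(comparison_peaks)) {
    hist_b <- dplyr::count(per_peak(comparison_peaks), .data$decile,
                           .drop = FALSE, name = "n")
    top <- length(decile_levels)
    res$top_decile_ratio <- hist$n[top] / hist_b$n[top]
  }
  structure(res, class = "repeat_fraction")
}

#' @export
print.repeat_fraction <- function(x, ...) {
  cat(sprintf("<repeat_fraction> %d peak(s); median %.1f%% repetitive\n",
              nrow(x$per_peak), median(x$per_peak$percent_repeat)))
  if (!is.null(x$top_decile_ratio)) {
    cat(sprintf("  top-decile (91-100%%) count ratio vs comparison set: %.2f\n",
                x$top_decile_ratio))
  }
  invisible(x)
}

#' Peak coverage of genes by finger-domain count
#'
#' For zinc-finger genes annotated with the number of tandemly repeated
#' finger domains in their 3' exon, computes the percentage of genes in
#' each finger-count class whose span is overlapped by at least one
#' peak.  Classes with no annotated gene are omitted rather than
#' reported as 0%.
#'
#' @param genes Gene tibble with an `n_fingers` column (genes with `NA`
#'   are dropped).
#' @param peaks Tibble of half-open intervals.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @param classes Finger-count classes to report (default 1:25).
#' @return A tibble with `n_fingers`, `n_genes`, `n_covered`, `percent`.
#' @export
finger_domain_association <- function(genes, peaks, min_overlap = 1,
                                      classes = 1:25) {
  g <- genes[!is.na(genes$n_fingers), , drop = FALSE]
  if (nrow(g) == 0) abort("no gene carries a finger-domain annotation")
  covered <- suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(g), as_granges(peaks),
                                 minoverlap = min_overlap)) > 0
  dplyr::bind_rows(lapply(classes, function(k) {
    sel <- g$n_fingers == k
    if (!any(sel)) return(NULL)
    tibble(n_fingers = k, n_genes = sum(sel), n_covered = sum(covered & sel),
           percent = 100 * sum(covered & sel) / sum(sel))
  }))
}

#' Mean of per-region maximum heights
#'
#' @param peaks A peak tibble with a `max_height` column.
#' @return The arithmetic mean maximum height.
#' @export
mean_max_height <- function(peaks) {
  if (!is.data.frame(peaks) || nrow(peaks) == 0) {
    abort("`peaks` must be a non-empty peak table")
  }
  if (!"max_height" %in% names(peaks)) abort("`peaks` lacks a `max_height` column")
  mean(peaks$max_height)
}

#' Fold difference in genome coverage
#'
#' The ratio of two total-coverage figures (bp covered by two peak
#' sets), rounded half-up to one decimal — the "fold difference" used to
#' compare broad-region calling with narrow peak calling.
#'
#' @param coverage_a,coverage_b Total covered bp (both > 0); the fold is
#'   `coverage_b / coverage_a`.
#' @return The fold, to one decimal.
#' @examples
#' fold_coverage_difference(3416942, 14139035) # 4.1
#' @export
fold_coverage_difference <- function(coverage_a, coverage_b) {
  if (any(coverage_a <= 0) || any(coverage_b <= 0)) {
    abort("coverage values must be positive")
  }
  round_half_up(coverage_b / coverage_a, 1)
}
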