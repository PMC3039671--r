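# Shared fixtures and independent brute-force oracles.  Every oracle here is
# deliberately naive (per-bp loops, all-pairs scans) and shares no code with
# the implementation it checks.

mk_tags <- function(chrom, pos, strand = "+", read_length = 36L) {
  out <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                        strand = rep_len(strand, length(pos)))
  attr(out, "read_length") <- read_length
  out
}

# Hand-built coverage track for tests that need exact bin values.
mk_track <- function(v, bin_size = 100L, chrom = "chrT", smoothed = FALSE) {
  structure(list(
    depth = setNames(list(as.numeric(v)), chrom),
    bin_size = as.integer(bin_size), extension = 1L,
    chrom_sizes = setNames(length(v) * as.integer(bin_size), chrom),
    normalized = FALSE, smoothed = smoothed
  ), class = "coverage_track")
}

rand_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 1e5,
                           min_len = 10, max_len = 2000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample(seq(min_len, max_len), n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + len)
}

# --- per-bp pileup oracle for build_coverage -------------------------------
bf_binned_pileup <- function(tags, L, bin_size, extension) {
  per_bp <- numeric(L)
  for (i in seq_len(nrow(tags))) {
    if (tags$strand[i] == "+") {
      s <- tags$pos[i]
      e <- s + extension - 1L
    } else {
      e <- tags$pos[i]
      s <- e - extension + 1L
    }
    s <- max(s, 0L); e <- min(e, L - 1L)
    if (s <= e) per_bp[(s + 1):(e + 1)] <- per_bp[(s + 1):(e + 1)] + 1
  }
  nb <- ceiling(L / bin_size)
  vapply(seq_len(nb), function(b) {
    lo <- (b - 1L) * bin_size + 1L
    hi <- min(b * bin_size, L)
    mean(per_bp[lo:hi])
  }, numeric(1))
}

# --- windowed-mean oracle for sliding_average ------------------------------
bf_window_mean <- function(x, window) {
  w <- (window - 1) / 2
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - w):min(length(x), i + w)])
  }, numeric(1))
}

# --- run/merge scanner oracle for regions_above ----------------------------
bf_regions_above <- function(v, bin_size, height, merge_gap, min_region_len) {
  above <- v >= height
  runs <- list()
  i <- 1
  while (i <= length(v)) {
    if (above[i]) {
      j <- i
      while (j < length(v) && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(runs) == 0) return(NULL)
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    prev <- merged[[length(merged)]]
    if ((r[1] - prev[2] - 1) * bin_size <= merge_gap) {
      merged[[length(merged)]] <- c(prev[1], r[2])
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  out <- do.call(rbind, lapply(merged, function(r) {
    bins <- v[r[1]:r[2]]
    c(start = (r[1] - 1) * bin_size, end = r[2] * bin_size,
      max_height = max(bins), mean_height = mean(bins))
  }))
  out <- out[out[, "end"] - out[, "start"] >= min_region_len, , drop = FALSE]
  if (nrow(out) == 0) NULL else out
}

# --- all-pairs overlap oracle ----------------------------------------------
bf_overlap_bp <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
}

bf_has_hit <- function(x, others, min_overlap) {
  sapply(seq_len(nrow(x)), function(i) {
    same <- others$chrom == x$chrom[i]
    any(bf_overlap_bp(x$start[i], x$end[i],
                      others$start[same], others$end[same]) >= min_overlap)
  })
}

# --- PWM scan oracle: score every window explicitly ------------------------
bf_motif_hits <- function(seq, mat, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    hits <- 0L
    L <- ncol(mat)
    if (nchar(s) < L) return(0L)
    for (p in 1:(nchar(s) - L + 1)) {
      win <- ch[p:(p + L - 1)]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      sc <- 0
      for (j in 1:L) sc <- sc + mat[win[j], j]
      if (sc >= threshold) hits <- hits + 1L
    }
    hits
  }
  rc <- paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
  score_one(seq) + score_one(rc)
}

# --- per-bp repeat membership oracle ---------------------------------------
bf_repeat_percent <- function(peak_start, peak_end, rep_start, rep_end) {
  bp <- seq(peak_start, peak_end - 1)
  inside <- rep(FALSE, length(bp))
  for (i in seq_along(rep_start)) {
    inside <- inside | (bp >= rep_start[i] & bp < rep_end[i])
  }
  100 * sum(inside) / length(bp)
}

# --- nearest-gene oracle: exhaustive application of the tie rules ----------
bf_nearest <- function(region, genes) {
  g <- genes[genes$chrom == region$chrom, ]
  if (nrow(g) == 0) return("none")
  gap <- pmax(0, g$start - region$end, region$start - g$end)
  tss_gap <- pmax(0, region$start - g$tss, g$tss - (region$end - 1))
  g$gene_id[order(gap, tss_gap, g$gene_id)][1]
}

# Jaccard between one truth domain and the union of called regions hitting it.
domain_jaccard <- function(truth_row, peaks) {
  p <- peaks[peaks$chrom == truth_row$chrom, ]
  ov <- pmax(0, pmin(p$end, truth_row$end) - pmax(p$start, truth_row$start))
  hit <- ov > 0
  if (!any(hit)) return(0)
  inter <- sum(ov)
  union <- sum(p$end[hit] - p$start[hit]) +
    (truth_row$end - truth_row$start) - inter
  inter / union
}
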