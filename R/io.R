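# Readers and writers for the plain-text formats the pipeline touches.
# Convention everywhere: 0-based half-open coordinates, exactly as in BED.
# Chromosome names are opaque tokens; no "chr" normalization is attempted.

split_bed_fields <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE), lineno = which(keep))
}

parse_coord <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: line %d: %s is not an integer coordinate (got '%s')",
      path, lineno[bad[1]], what, x[bad[1]]
    ))
  }
  v
}

#' Read mapped sequence tags from a BED file
#'
#' Parses a BED3/BED6 file of mapped tags into a tag table.  The tag 5'
#' position is the BED `start` for `+` strand tags and `end - 1` for `-`
#' strand tags, so that fragment extension can proceed in the read
#' direction.  Input line order is irrelevant: the result is sorted by
#' chromosome and position.
#'
#' @param path Path to a BED3/BED6 file.  Lines starting with `#`,
#'   `track` or `browser` are skipped.  A missing strand column defaults
#'   to `+` with a warning, since the caller extends tags directionally.
#' @return A tibble with columns `chrom`, `pos` (0-based 5' position) and
#'   `strand`, carrying the median mapped read length as the
#'   `read_length` attribute.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t136\t.\t0\t-", bed)
#' read_tag_bed(bed)
#' @export
read_tag_bed <- function(path) {
  p <- split_bed_fields(path)
  if (length(p$fields) == 0) {
    out <- tibble(chrom = character(), pos = integer(), strand = character())
    attr(out, "read_length") <- 0L
    return(out)
  }
  nf <- lengths(p$fields)
  if (any(nf < 3)) {
    i <- which(nf < 3)[1]
    abort(sprintf("%s: line %d: expected >= 3 tab-separated fields, got %d",
                  path, p$lineno[i], nf[i]))
  }
  chrom <- vapply(p$fields, `[[`, character(1), 1L)
  start <- parse_coord(vapply(p$fields, `[[`, character(1), 2L), path, p$lineno, "start")
  end <- parse_coord(vapply(p$fields, `[[`, character(1), 3L), path, p$lineno, "end")
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: start (%d) >= end (%d)",
                  path, p$lineno[bad[1]], start[bad[1]], end[bad[1]]))
  }
  if (any(start < 0)) {
    i <- which(start < 0)[1]
    abort(sprintf("%s: line %d: negative start", path, p$lineno[i]))
  }
  if (all(nf >= 6)) {
    strand <- vapply(p$fields, `[[`, character(1), 6L)
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad) > 0) {
      warn(sprintf("%s: %d line(s) without a usable strand; defaulting to '+'",
                   path, length(bad)))
      strand[bad] <- "+"
    }
  } else {
    warn(sprintf("%s: no strand column; defaulting all tags to '+'", path))
    strand <- rep("+", length(chrom))
  }
  pos <- ifelse(strand == "+", start, end - 1L)
  ord <- order(chrom, pos)
  out <- tibble(chrom = chrom[ord], pos = as.integer(pos[ord]), strand = strand[ord])
  attr(out, "read_length") <- as.integer(median(end - start))
  out
}

#' Write mapped tags to a BED6 file
#'
#' Inverse of [read_tag_bed()]: each tag becomes a read-length interval
#' anchored at its 5' position (so a `-` strand tag at position `p`
#' spans `[p - read_length + 1, p + 1)`).
#'
#' @param tags A tag tibble (`chrom`, `pos`, `strand`).
#' @param path Output file path.
#' @param read_length Read length in bp; defaults to the tag set's
#'   `read_length` attribute (36 when absent).
#' @return `path`, invisibly.
#' @export
write_tag_bed <- function(tags, path, read_length = NULL) {
  rl <- read_length %||% tag_read_length(tags)
  if (rl < 1) rl <- 36L
  # clip reads hanging over the chromosome start; the 5' anchor (BED end - 1
  # for minus-strand tags) is preserved
  start <- pmax(ifelse(tags$strand == "+", tags$pos, tags$pos - rl + 1L), 0L)
  writeLines(sprintf("%s\t%d\t%d\t.\t0\t%s", tags$chrom, as.integer(start),
                     as.integer(start + rl), tags$strand), path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' General-purpose interval reader used for repeat annotations and
#' previously called regions.  Only the first three columns are
#' interpreted; name/score/strand are carried through when present.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_region_bed <- function(path) {
  p <- split_bed_fields(path)
  if (length(p$fields) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  nf <- lengths(p$fields)
  if (any(nf < 3)) {
    i <- which(nf < 3)[1]
    abort(sprintf("%s: line %d: expected >= 3 tab-separated fields, got %d",
                  path, p$lineno[i], nf[i]))
  }
  chrom <- vapply(p$fields, `[[`, character(1), 1L)
  start <- parse_coord(vapply(p$fields, `[[`, character(1), 2L), path, p$lineno, "start")
  end <- parse_coord(vapply(p$fields, `[[`, character(1), 3L), path, p$lineno, "end")
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: invalid interval [%d, %d)",
                  path, p$lineno[bad[1]], start[bad[1]], end[bad[1]]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(p$fields, `[[`, character(1), 4L)
  if (all(nf >= 5)) {
    out$score <- suppressWarnings(as.numeric(vapply(p$fields, `[[`, character(1), 5L)))
  }
  if (all(nf >= 6)) out$strand <- vapply(p$fields, `[[`, character(1), 6L)
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Write called regions to a BED6 file
#'
#' Regions are written as `chrom start end name score strand` with names
#' `peak_1 ... peak_n`, score equal to the region's maximum height
#' rounded to an integer (0 when no height column is present), and `.`
#' strand.  Coordinates round-trip losslessly through
#' [read_region_bed()].
#'
#' @param regions A tibble of intervals, optionally with `max_height`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  check_intervals(regions)
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- if ("max_height" %in% names(regions)) round(regions$max_height) else 0
  lines <- sprintf("%s\t%d\t%d\tpeak_%d\t%d\t.",
                   regions$chrom, as.integer(regions$start), as.integer(regions$end),
                   seq_len(nrow(regions)), as.integer(score))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene table
#'
#' Reads a tab-separated gene annotation with a header line
#' `gene_id chrom strand txStart txEnd [n_fingers]` and `#` comments.
#' Coordinates are 0-based half-open, matching the BED convention used
#' everywhere else.  The transcription start site is `txStart` for `+`
#' strand genes and `txEnd - 1` for `-` strand genes.  The optional
#' `n_fingers` column carries the number of tandemly repeated
#' zinc-finger domains in the gene's 3' exon.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss` and `n_fingers` (`NA` when unannotated).
#' @export
read_gene_table <- function(path) {
  g <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("gene_id", "chrom", "strand", "txStart", "txEnd")
  miss <- setdiff(need, names(g))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  dup <- g$gene_id[duplicated(g$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicate gene_id: %s", path, dup[1]))
  }
  if (any(!g$strand %in% c("+", "-"))) {
    abort(sprintf("%s: strand must be '+' or '-'", path))
  }
  if (any(g$txStart >= g$txEnd) || any(g$txStart < 0)) {
    i <- which(g$txStart >= g$txEnd | g$txStart < 0)[1]
    abort(sprintf("%s: gene %s: invalid span [%d, %d)", path, g$gene_id[i],
                  g$txStart[i], g$txEnd[i]))
  }
  nf <- if ("n_fingers" %in% names(g)) {
    suppressWarnings(as.integer(g$n_fingers))
  } else {
    rep(NA_integer_, nrow(g))
  }
  if (any(!is.na(nf) & nf < 0)) {
    abort(sprintf("%s: n_fingers must be >= 0", path))
  }
  tibble(
    gene_id = as.character(g$gene_id),
    chrom = as.character(g$chrom),
    strand = g$strand,
    start = as.integer(g$txStart),
    end = as.integer(g$txEnd),
    tss = as.integer(ifelse(g$strand == "+", g$txStart, g$txEnd - 1L)),
    n_fingers = nf
  )
}

#' Write a gene table
#'
#' Inverse of [read_gene_table()]; genes without a finger-domain
#' annotation get an empty `n_fingers` field.
#'
#' @param genes A gene tibble as returned by [read_gene_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    txStart = genes$start, txEnd = genes$end, n_fingers = genes$n_fingers
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# 0-based half-open coordinates (BED convention)", con)
  readr::write_tsv(out, con, na = "", progress = FALSE)
  invisible(path)
}

#' Read per-position allele counts
#'
#' Tab-separated with header
#' `chrom pos wt_base var_base wt_count var_count other_count`; `pos` is
#' a 0-based position.  Counts are reads supporting the reference base,
#' the variant base, and any other base.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per position.
#' @export
read_allele_counts <- function(path) {
  a <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("chrom", "pos", "wt_count", "var_count")
  miss <- setdiff(need, names(a))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  if (!"other_count" %in% names(a)) a$other_count <- 0L
  if (any(a$wt_count < 0 | a$var_count < 0 | a$other_count < 0)) {
    abort(sprintf("%s: negative allele counts", path))
  }
  as_tibble(a)
}

#' Extract region sequences from a FASTA file
#'
#' Pulls the DNA sequence under each interval from an indexed-in-memory
#' FASTA, for motif scanning.
#'
#' @param fasta_path Path to a FASTA file whose record names match
#'   `regions$chrom`.
#' @param regions A tibble of half-open intervals.
#' @return `regions` with an added `seq` character column.
#' @export
region_sequences <- function(fasta_path, regions) {
  check_intervals(regions)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  miss <- setdiff(unique(regions$chrom), names(genome))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing sequence(s): %s", fasta_path,
                  paste(miss, collapse = ", ")))
  }
  regions$seq <- vapply(seq_len(nrow(regions)), function(i) {
    as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                    start = regions$start[i] + 1L,
                                    end = regions$end[i]))
  }, character(1))
  regions
}
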