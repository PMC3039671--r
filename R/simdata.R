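# Synthetic ChIP-seq experiments with known ground truth: planted broad or
# jagged enrichment domains, copy-number segments, over-sequenced hotspots and
# a uniform Poisson-like background.  Tag placement is multinomial over a
# piecewise-constant bp weight function, so tag totals are exact and per-bin
# count conservation can be checked directly.

#' Configuration of a synthetic ChIP-seq experiment
#'
#' @param chrom_sizes Named chromosome lengths in bp (default two 5 Mb
#'   chromosomes — large enough for megabase background sampling bins,
#'   small enough for fast desk-scale runs).
#' @param planted_regions Tibble (`chrom`, `start`, `end`, `fold`,
#'   `profile`) of enrichment domains; `profile` is `"block"` (uniform
#'   fold) or `"jagged"` (500 bp sub-blocks alternating between the fold
#'   and background, emulating the "mountain range" profiles of
#'   spreading histone marks).
#' @param cn_segments Tibble (`chrom`, `start`, `end`, `copy_number`) of
#'   duplicated/deleted segments affecting both channels.
#' @param oversequenced Tibble (`chrom`, `start`, `end`, `fold`) of
#'   artifact hotspots inflating both channels.
#' @param background_rate Relative background weight per bp (only
#'   ratios matter; tag totals are fixed by `n_*_tags`).
#' @param n_chip_tags,n_input_tags Tag counts per channel (default 5e5,
#'   giving a mean fragment depth near 17 on the default genome).
#' @param read_length,fragment_length Read and sonicated fragment
#'   lengths in bp (defaults 36 and 350).
#' @param seed Integer seed fixing all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_sizes = c(sim1 = 5e6, sim2 = 5e6),
                       planted_regions = NULL, cn_segments = NULL,
                       oversequenced = NULL, background_rate = 1,
                       n_chip_tags = 5e5, n_input_tags = 5e5,
                       read_length = 36, fragment_length = 350, seed = 1L) {
  empty_fold <- tibble(chrom = character(), start = numeric(),
                       end = numeric(), fold = numeric())
  planted_regions <- planted_regions %||%
    dplyr::mutate(empty_fold, profile = character())
  cn_segments <- cn_segments %||%
    tibble(chrom = character(), start = numeric(), end = numeric(),
           copy_number = numeric())
  oversequenced <- oversequenced %||% empty_fold
  if (nrow(planted_regions) > 0) {
    if (!"profile" %in% names(planted_regions)) planted_regions$profile <- "block"
    check_intervals(planted_regions)
    if (any(planted_regions$fold <= 0)) abort("enrichment folds must be > 0")
    if (any(!planted_regions$profile %in% c("block", "jagged"))) {
      abort("`profile` must be 'block' or 'jagged'")
    }
    if (any(planted_regions$end > chrom_sizes[planted_regions$chrom])) {
      abort("planted regions must lie within chromosome bounds")
    }
  }
  if (n_chip_tags < 1 || n_input_tags < 1) {
    abort("tag counts must be >= 1")
  }
  structure(list(
    chrom_sizes = chrom_sizes, planted_regions = planted_regions,
    cn_segments = cn_segments, oversequenced = oversequenced,
    background_rate = background_rate,
    n_chip_tags = as.integer(n_chip_tags),
    n_input_tags = as.integer(n_input_tags),
    read_length = as.integer(read_length),
    fragment_length = as.integer(fragment_length),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Piecewise-constant weight segmentation of one chromosome: returns a tibble
# of elementary segments with input and chip per-bp weights.
weight_segments <- function(config, ch) {
  L <- config$chrom_sizes[[ch]]
  planted <- config$planted_regions[config$planted_regions$chrom == ch, ,
                                    drop = FALSE]
  cn <- config$cn_segments[config$cn_segments$chrom == ch, , drop = FALSE]
  os <- config$oversequenced[config$oversequenced$chrom == ch, , drop = FALSE]
  breaks <- c(0, L, cn$start, cn$end, os$start, os$end)
  enrich_spans <- NULL
  for (i in seq_len(nrow(planted))) {
    s <- planted$start[i]; e <- planted$end[i]
    if (planted$profile[i] == "block") {
      enrich_spans <- rbind(enrich_spans, c(s, e, planted$fold[i]))
    } else {
      # 500 bp sub-blocks alternating enriched / background within the domain.
      sub <- seq(s, e, by = 500)
      if (tail(sub, 1) < e) sub <- c(sub, e)
      for (k in seq_len(length(sub) - 1)) {
        f <- if (k %% 2 == 1) planted$fold[i] else 1
        enrich_spans <- rbind(enrich_spans, c(sub[k], sub[k + 1], f))
      }
    }
  }
  if (!is.null(enrich_spans)) breaks <- c(breaks, enrich_spans[, 1], enrich_spans[, 2])
  breaks <- sort(unique(pmin(pmax(breaks, 0), L)))
  seg <- tibble(start = breaks[-length(breaks)], end = breaks[-1])
  mid <- (seg$start + seg$end) / 2
  lookup <- function(spans_start, spans_end, values, default = 1) {
    out <- rep(default, length(mid))
    for (i in seq_along(spans_start)) {
      out[mid >= spans_start[i] & mid < spans_end[i]] <- values[i]
    }
    out
  }
  cn_w <- lookup(cn$start, cn$end, cn$copy_number)
  os_w <- lookup(os$start, os$end, os$fold)
  en_w <- if (is.null(enrich_spans)) {
    rep(1, length(mid))
  } else {
    lookup(enrich_spans[, 1], enrich_spans[, 2], enrich_spans[, 3])
  }
  seg$chrom <- ch
  seg$w_input <- config$background_rate * cn_w * os_w
  seg$w_chip <- config$background_rate * cn_w * os_w * en_w
  seg
}

place_tags <- function(seg, n_tags, weight_col) {
  w <- seg[[weight_col]] * (seg$end - seg$start)
  counts <- as.vector(rmultinom(1, n_tags, prob = w))
  idx <- rep(seq_len(nrow(seg)), counts)
  pos <- floor(seg$start[idx] + runif(length(idx)) * (seg$end[idx] - seg$start[idx]))
  tibble(chrom = seg$chrom[idx], pos = as.integer(pos),
         strand = sample(c("+", "-"), length(idx), replace = TRUE))
}

#' Simulate a ChIP-seq experiment with known truth
#'
#' Input tags are placed multinomially with per-bp weight proportional
#' to background rate x copy number x over-sequencing inflation; ChIP
#' tags additionally carry the planted enrichment fold inside each
#' domain.  Jagged domains modulate the fold in alternating 500 bp
#' sub-blocks.  Deterministic per `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with tag tibbles `chip` and `input` (sorted, with a
#'   `read_length` attribute) and `truth`, a list holding the planted
#'   domains, copy-number segments, over-sequenced spans and the config.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  segs <- dplyr::bind_rows(lapply(names(config$chrom_sizes),
                                  function(ch) weight_segments(config, ch)))
  out <- withr::with_seed(config$seed, {
    list(chip = place_tags(segs, config$n_chip_tags, "w_chip"),
         input = place_tags(segs, config$n_input_tags, "w_input"))
  })
  chip <- dplyr::arrange(out$chip, .data$chrom, .data$pos)
  input <- dplyr::arrange(out$input, .data$chrom, .data$pos)
  attr(chip, "read_length") <- config$read_length
  attr(input, "read_length") <- config$read_length
  list(
    chip = chip, input = input,
    truth = list(planted = config$planted_regions,
                 cn_segments = config$cn_segments,
                 oversequenced = config$oversequenced,
                 chrom_sizes = config$chrom_sizes,
                 config = config)
  )
}

#' Preset simulation configurations
#'
#' `"broad-domains"` plants 20 jagged 10-50 kb domains at fold 8 on two
#' 5 Mb chromosomes, the stock test-bed for broad-mode recovery and the
#' narrow-versus-broad coverage contrast.  `"null"` is one 2 Mb
#' chromosome with no enrichment at all, so ChIP and input are two
#' draws from the same distribution.
#'
#' @param preset Preset name.
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
sim_preset <- function(preset = c("broad-domains", "null"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "null") {
    return(sim_config(chrom_sizes = c(sim1 = 2e6), n_chip_tags = 5e4,
                      n_input_tags = 5e4, seed = seed))
  }
  chrom_sizes <- c(sim1 = 5e6, sim2 = 5e6)
  # Ten 500 kb slots per chromosome; domain length drawn per slot so domains
  # stay far apart relative to the merge gap.
  planted <- withr::with_seed(seed, {
    dplyr::bind_rows(lapply(names(chrom_sizes), function(ch) {
      slot <- seq(0, 4.5e6, by = 5e5)
      len <- round(runif(length(slot), 1e4, 5e4))
      start <- slot + 2e5
      tibble(chrom = ch, start = start, end = start + len, fold = 8,
             profile = "jagged")
    }))
  })
  sim_config(chrom_sizes = chrom_sizes, planted_regions = planted, seed = seed)
}

#' Simulate a zinc-finger gene catalog with coverage tied to domain count
#'
#' Generates genes whose finger-domain counts are uniform over a range
#' and covers each gene with a peak with probability `coverage_trend(k)`
#' for a gene with `k` fingers — the planted-trend test-bed for
#' [finger_domain_association()].
#'
#' @param n_genes Number of genes.
#' @param finger_count_range Two-element range of finger counts
#'   (default `c(1, 25)`).
#' @param coverage_trend Function mapping a finger count to a coverage
#'   probability; default a logistic rising around 8 fingers, so genes
#'   with few fingers are rarely covered and genes with more than 15
#'   almost always are.
#' @param seed Integer seed.
#' @return A list with `genes` (gene tibble with `n_fingers`) and
#'   `peaks` (intervals covering the selected genes).
#' @export
simulate_gene_catalog <- function(n_genes, finger_count_range = c(1, 25),
                                  coverage_trend = function(k) {
                                    stats::plogis((k - 8) / 2.5)
                                  },
                                  seed = 1L) {
  if (n_genes < 1) abort("`n_genes` must be >= 1")
  withr::with_seed(seed, {
    k <- sample(seq(finger_count_range[1], finger_count_range[2]), n_genes,
                replace = TRUE)
    start <- (seq_len(n_genes) - 1) * 30000
    genes <- tibble(
      gene_id = sprintf("znf%04d", seq_len(n_genes)),
      chrom = "sim1", strand = "+",
      start = as.integer(start), end = as.integer(start + 20000),
      tss = as.integer(start), n_fingers = as.integer(k)
    )
    covered <- runif(n_genes) < coverage_trend(k)
    peaks <- tibble(
      chrom = "sim1",
      start = genes$start[covered] + 10000L,
      end = genes$end[covered] + 2000L
    )
    list(genes = genes, peaks = peaks)
  })
}

#' Simulate per-position allele counts
#'
#' Heterogeneous positions draw their reference-allele fraction from
#' Uniform(0.35, 0.65); fixed positions put Uniform(0.95, 1) of the mass
#' on a majority allele (the variant with probability
#' `1 - prob_wt_major`, mirroring the predominance of genome-fixed SNPs
#' among expressed fixed positions).  Read counts are binomial at a
#' depth uniform over `depth_range`.
#'
#' @param n_sites Number of positions.
#' @param fraction_heterogeneous Fraction of positions simulated as
#'   heterogeneous (both alleles expressed); default 29/72.
#' @param depth_range Two-element range of total read depth (default
#'   `c(20, 100)`).
#' @param seed Integer seed.
#' @param prob_wt_major Probability that a fixed site fixes the
#'   reference allele (default 3/43).
#' @return A tibble of allele counts with the planted `true_class`.
#' @export
simulate_allele_counts <- function(n_sites, fraction_heterogeneous = 29 / 72,
                                   depth_range = c(20, 100), seed = 1L,
                                   prob_wt_major = 3 / 43) {
  if (fraction_heterogeneous < 0 || fraction_heterogeneous > 1) {
    abort("`fraction_heterogeneous` must be in [0, 1]")
  }
  withr::with_seed(seed, {
    n_het <- round(n_sites * fraction_heterogeneous)
    het <- sample(c(rep(TRUE, n_het), rep(FALSE, n_sites - n_het)))
    wt_major <- runif(n_sites) < prob_wt_major
    major_frac <- ifelse(het, runif(n_sites, 0.35, 0.65),
                         runif(n_sites, 0.95, 1))
    wt_frac <- ifelse(het | wt_major, major_frac, 1 - major_frac)
    depth <- sample(seq(depth_range[1], depth_range[2]), n_sites,
                    replace = TRUE)
    wt <- rbinom(n_sites, depth, wt_frac)
    tibble(
      chrom = "sim19",
      pos = sort(sample.int(6e7, n_sites)),
      wt_base = "A", var_base = "G",
      wt_count = wt, var_count = depth - wt, other_count = 0L,
      true_class = ifelse(het, "heterogeneous",
                          ifelse(wt_major, "wt_fixed", "variant_fixed"))
    )
  })
}
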