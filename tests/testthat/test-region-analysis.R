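# Downstream region analytics against brute-force oracles.

test_that("interval Venn counts follow the qualifying-overlap rule", {
  a <- tibble::tibble(chrom = "c", start = 0L, end = 100L)
  b <- tibble::tibble(chrom = "c", start = 50L, end = 150L)
  v <- intersect_sets(a, b, min_overlap = 1)
  expect_equal(v$both, 1)
  expect_equal(v$a_only, 0)
  expect_equal(v$b_only, 0)

  disjoint <- intersect_sets(a, dplyr::mutate(b, start = 500L, end = 600L))
  expect_equal(disjoint$both, 0)
  expect_equal(disjoint$a_only, 1)
  expect_equal(disjoint$b_only, 1)

  # a 49 bp overlap does not qualify at min_overlap = 50
  expect_equal(intersect_sets(a, tibble::tibble(chrom = "c", start = 51L,
                                                end = 150L),
                              min_overlap = 50)$both, 0)
})

test_that("Venn classification is symmetric and matches the all-pairs oracle", {
  set.seed(61)
  a <- rand_intervals(400)
  b <- rand_intervals(400)
  for (mo in c(1, 50)) {
    v <- intersect_sets(a, b, min_overlap = mo)
    hit_a <- bf_has_hit(a, b, mo)
    hit_b <- bf_has_hit(b, a, mo)
    expect_equal(v$a_only, sum(!hit_a))
    expect_equal(v$b_only, sum(!hit_b))
    expect_equal(v$a_shared, sum(hit_a))
    expect_equal(v$b_shared, sum(hit_b))
    expect_equal(v$a_only + v$a_shared, nrow(a))

    w <- intersect_sets(b, a, min_overlap = mo)
    expect_equal(w$a_only, v$b_only)
    expect_equal(w$b_only, v$a_only)
    expect_equal(w$both, v$both)
  }
})

test_that("tag densities are counts per kilobase with aggregate pooling", {
  region <- tibble::tibble(chrom = "c", start = 1000L, end = 3000L)
  tags <- mk_tags("c", seq(1100, 2900, length.out = 10))
  d <- tag_density_per_kb(tags, region)
  expect_equal(d$n_tags, 10L)
  expect_equal(d$density, 5.0)

  none <- tag_density_per_kb(mk_tags("other", 5L), region)
  expect_equal(none$density, 0)
  expect_error(tag_density_per_kb(tags, region[0, ]), "non-empty")

  # aggregate density is invariant under splitting a region in half
  halves <- tibble::tibble(chrom = "c", start = c(1000L, 2000L),
                           end = c(2000L, 3000L))
  expect_equal(attr(tag_density_per_kb(tags, halves), "aggregate_density"),
               attr(tag_density_per_kb(tags, region), "aggregate_density"))
})

test_that("per-region tag counts match a brute-force membership scan", {
  set.seed(62)
  tags <- mk_tags(sample(c("c1", "c2"), 5000, TRUE),
                  sample.int(1e5, 5000, TRUE) - 1L)
  regions <- rand_intervals(100)
  d <- tag_density_per_kb(tags, regions)
  want <- vapply(seq_len(nrow(regions)), function(i) {
    sum(tags$chrom == regions$chrom[i] & tags$pos >= regions$start[i] &
          tags$pos < regions$end[i])
  }, numeric(1))
  expect_equal(d$n_tags, as.integer(want))
})

genes_fixture <- tibble::tibble(
  gene_id = c("g1", "g2"), chrom = "c", strand = c("+", "-"),
  start = c(10000L, 40000L), end = c(20000L, 50000L),
  tss = c(10000L, 49999L), n_fingers = c(3L, 12L)
)

test_that("location classes follow promoter > intragenic > intergenic", {
  r <- tibble::tibble(chrom = "c",
                      start = c(9800L, 15000L, 30000L, 49900L),
                      end = c(10200L, 15500L, 30500L, 50100L))
  cls <- classify_location(r, genes_fixture, promoter_halfwidth = 500)
  expect_equal(cls$location,
               c("promoter", "intragenic", "intergenic", "promoter"))
})

test_that("location classification matches a per-region rule oracle", {
  set.seed(63)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:50), chrom = sample(c("c1", "c2"), 50, TRUE),
    strand = sample(c("+", "-"), 50, TRUE)
  )
  genes$start <- sample.int(9e4, 50) - 1L
  genes$end <- genes$start + sample(2000:20000, 50, TRUE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  regions <- rand_intervals(500)
  got <- classify_location(regions, genes, 500)$location
  want <- vapply(seq_len(nrow(regions)), function(i) {
    g <- genes[genes$chrom == regions$chrom[i], ]
    prom <- any(bf_overlap_bp(regions$start[i], regions$end[i],
                              g$tss - 500, g$tss + 501) > 0)
    body <- any(bf_overlap_bp(regions$start[i], regions$end[i],
                              g$start, g$end) > 0)
    if (prom) "promoter" else if (body) "intragenic" else "intergenic"
  }, character(1))
  expect_equal(got, want)
})

test_that("nearest gene minimizes the gap with TSS and id tie-breaks", {
  inside <- tibble::tibble(chrom = "c", start = 12000L, end = 13000L)
  expect_equal(nearest_gene(inside, genes_fixture)$gene_id, "g1")
  expect_equal(nearest_gene(inside, genes_fixture)$gene_distance, 0)

  # equidistant from both spans (gap 500); g2's TSS is nearer
  mid <- tibble::tibble(chrom = "c", start = 20500L, end = 39500L)
  g <- genes_fixture
  g$tss <- c(10000L, 40000L)
  expect_equal(nearest_gene(mid, g)$gene_id, "g2")
  # span gaps AND TSS gaps both tied (10500 bp each): lexicographic id wins
  expect_equal(nearest_gene(mid, genes_fixture)$gene_id, "g1")

  off <- tibble::tibble(chrom = "elsewhere", start = 0L, end = 10L)
  expect_equal(nearest_gene(off, genes_fixture)$gene_id, "none")
})

test_that("nearest gene agrees with the exhaustive oracle", {
  set.seed(64)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", sample(999, 60)),
    chrom = sample(c("c1", "c2"), 60, TRUE),
    strand = "+"
  )
  genes$start <- sample.int(9e4, 60) - 1L
  genes$end <- genes$start + sample(1000:15000, 60, TRUE)
  genes$tss <- genes$start
  regions <- rand_intervals(1000)
  got <- nearest_gene(regions, genes)$gene_id
  want <- vapply(seq_len(nrow(regions)), function(i) {
    bf_nearest(regions[i, ], genes)
  }, character(1))
  expect_equal(got, want)
})

test_that("repeat fractions use the union of repeats and decile bins", {
  peak <- tibble::tibble(chrom = "c", start = 0L, end = 1000L)
  clean <- repeat_fraction_histogram(peak, rand_intervals(5, "other"))
  expect_equal(clean$per_peak$percent_repeat, 0)
  expect_equal(as.character(clean$per_peak$decile), "[0,10]")

  # overlapping repeats must not double count: 950 of 1000 bp covered
  reps <- tibble::tibble(chrom = "c", start = c(0L, 400L, 900L),
                         end = c(500L, 950L, 950L))
  r <- repeat_fraction_histogram(peak, reps)
  expect_equal(r$per_peak$percent_repeat, 95)
  expect_equal(as.character(r$per_peak$decile), "(90,100]")
  expect_equal(sum(r$histogram$n), 1)

  # fragmenting the repeat annotation changes nothing
  frag <- tibble::tibble(chrom = "c",
                         start = c(0L, 250L, 400L, 600L, 900L),
                         end = c(300L, 500L, 700L, 950L, 950L))
  expect_equal(repeat_fraction_histogram(peak, frag)$per_peak$percent_repeat, 95)

  # top-decile ratio against a comparison set
  lowrep <- tibble::tibble(chrom = "c", start = c(0L, 2000L, 4000L, 6000L),
                           end = c(1000L, 3000L, 5000L, 7000L))
  both <- repeat_fraction_histogram(dplyr::bind_rows(peak, peak, peak),
                                    reps, comparison_peaks = peak)
  expect_equal(both$top_decile_ratio, 3)
})

test_that("repeat percentages match the per-bp membership oracle", {
  set.seed(65)
  peaks <- rand_intervals(60, max_pos = 2e4, min_len = 50, max_len = 1500)
  reps <- rand_intervals(40, max_pos = 2e4, min_len = 20, max_len = 800)
  got <- repeat_fraction_histogram(peaks, reps)$per_peak$percent_repeat
  want <- vapply(seq_len(nrow(peaks)), function(i) {
    same <- reps$chrom == peaks$chrom[i]
    bf_repeat_percent(peaks$start[i], peaks$end[i],
                      reps$start[same], reps$end[same])
  }, numeric(1))
  expect_equal(got, want)
})

test_that("finger-domain coverage percentages handle edge cases", {
  genes <- genes_fixture
  peaks0 <- tibble::tibble(chrom = character(), start = integer(),
                           end = integer())
  none <- finger_domain_association(genes, peaks0)
  expect_equal(none$percent, c(0, 0))
  expect_equal(none$n_fingers, c(3, 12))   # absent classes omitted, not 0%

  all_cov <- finger_domain_association(
    genes, tibble::tibble(chrom = "c", start = 0L, end = 60000L))
  expect_equal(all_cov$percent, c(100, 100))

  unannotated <- dplyr::mutate(genes, n_fingers = NA_integer_)
  expect_error(finger_domain_association(unannotated, peaks0), "annotation")
})

test_that("height summaries and coverage folds compute correctly", {
  expect_equal(mean_max_height(tibble::tibble(max_height = 7)), 7)
  expect_equal(mean_max_height(tibble::tibble(max_height = c(2, 4))), 3)
  expect_error(mean_max_height(tibble::tibble(max_height = numeric(0))),
               "non-empty")

  expect_equal(fold_coverage_difference(123456, 123456), 1.0)
  # rounding is half-up at one decimal
  expect_equal(fold_coverage_difference(100, 115), 1.2)
  expect_equal(fold_coverage_difference(100, 114), 1.1)
  expect_error(fold_coverage_difference(0, 10), "positive")
})
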