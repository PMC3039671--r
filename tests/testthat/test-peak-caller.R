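# Shuffle-based FDR calibration and region extraction.

test_that("background shuffling conserves per-sampling-bin counts exactly", {
  set.seed(41)
  sizes <- c(a = 6e5, b = 4e5)
  tags <- mk_tags(sample(c("a", "b"), 10000, TRUE, prob = c(0.6, 0.4)),
                  sample.int(4e5, 10000, TRUE) - 1L,
                  sample(c("+", "-"), 10000, TRUE))
  n_bins <- 100
  bg <- make_background(tags, n_bins, sizes, seed = 9)

  expect_equal(nrow(bg), nrow(tags))
  expect_equal(table(bg$strand), table(tags$strand))
  # per-bin histogram oracle, recomputing the bin layout independently
  per_chrom <- pmax(round(n_bins * sizes / sum(sizes)), 1)
  for (ch in names(sizes)) {
    w <- sizes[[ch]] / per_chrom[[ch]]
    before <- table(factor(floor(tags$pos[tags$chrom == ch] / w),
                           levels = 0:(per_chrom[[ch]] - 1)))
    after <- table(factor(floor(bg$pos[bg$chrom == ch] / w),
                          levels = 0:(per_chrom[[ch]] - 1)))
    expect_equal(as.vector(after), as.vector(before))
  }

  expect_identical(make_background(tags, n_bins, sizes, seed = 9), bg)
  expect_false(identical(make_background(tags, n_bins, sizes, seed = 10), bg))
  expect_error(make_background(tags, 2e6, sizes), "resolution")
})

test_that("region extraction merges across gaps and drops short runs", {
  tr <- mk_track(c(0, 0, 3, 4, 3, 0, 2, 0))
  one <- regions_above(tr, height = 2, merge_gap = 100, min_region_len = 100)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(200L, 700L))
  expect_equal(one$max_height, 4)
  expect_equal(one$mean_height, mean(c(3, 4, 3, 0, 2)))
  expect_equal(one$area, sum(c(3, 4, 3, 0, 2)) * 100)

  two <- regions_above(tr, height = 2, merge_gap = 0, min_region_len = 100)
  expect_equal(nrow(two), 2)
  expect_equal(two$start, c(200L, 600L))
  expect_equal(two$end, c(500L, 700L))

  long_only <- regions_above(tr, 2, merge_gap = 0, min_region_len = 200)
  expect_equal(nrow(long_only), 1)

  expect_equal(nrow(regions_above(tr, 10)), 0)
  expect_error(regions_above(tr, 0), "positive")
})

test_that("region extraction matches a brute-force run scanner", {
  set.seed(42)
  v <- rpois(10000, 1.2)
  tr <- mk_track(v, 50)
  for (params in list(c(2, 0, 0), c(2, 100, 150), c(3, 200, 300))) {
    got <- regions_above(tr, params[1], params[2], params[3])
    want <- bf_regions_above(v, 50, params[1], params[2], params[3])
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, as.integer(want[, "start"]))
      expect_equal(got$end, as.integer(want[, "end"]))
      expect_equal(got$max_height, unname(want[, "max_height"]))
      expect_equal(got$mean_height, unname(want[, "mean_height"]))
    }
  }
})

planted_block_sim <- function(seed) {
  simulate_experiment(sim_config(
    chrom_sizes = c(simA = 1e6),
    planted_regions = tibble::tibble(chrom = "simA", start = 4e5, end = 4.3e5,
                                     fold = 20, profile = "block"),
    n_chip_tags = 3000, n_input_tags = 3000, seed = seed
  ))
}

test_that("one planted block calibrates between noise and its own height", {
  for (seed in c(51, 52, 53)) {
    sim <- planted_block_sim(seed)
    # a lone ChIP region over an empty background is only acceptable at
    # target FDR >= 1/(2 * n_background_draws)
    cfg <- peak_call_config(mode = "broad", fdr = 0.2, seed = seed)
    res <- call_peaks(sim$chip, sim$input, cfg, chrom_sizes = c(simA = 1e6))
    block_height <- 20 * 3000 * 350 / 1e6   # fold x mean background depth
    expect_gte(res$calibration$height_cutoff, 2)
    expect_lte(res$calibration$height_cutoff, block_height)
    # the block always comes out; at this lenient FDR a few
    # background-level regions may ride along
    pk <- tidy(res)
    expect_lte(nrow(pk), 4)
    expect_true(any(bf_overlap_bp(pk$start, pk$end, 4e5, 4.3e5) > 0))
  }
})

test_that("the returned cutoff is the first candidate meeting the target", {
  sim <- planted_block_sim(54)
  for (target in c(0.2, 1.0)) {
    res <- call_peaks(sim$chip, sim$input,
                      peak_call_config(mode = "broad", fdr = target, seed = 54),
                      chrom_sizes = c(simA = 1e6))
    tab <- tidy(res$calibration)
    at <- which(tab$height == res$calibration$height_cutoff)
    expect_lte(tab$empirical_fdr[at], target)
    if (at > 1) expect_true(all(tab$empirical_fdr[seq_len(at - 1)] > target))
  }
})

test_that("null data yields a calibration failure or a near-one FDR", {
  sim <- simulate_experiment(sim_preset("null", seed = 55))
  cfg <- peak_call_config(mode = "broad", fdr = 0.01, seed = 55)
  chip <- sliding_average(build_coverage(sim$chip, cfg$bin_size, cfg$extension,
                                         c(sim1 = 2e6)), 9)
  out <- tryCatch(calibrate_height_cutoff(chip, sim$input, cfg),
                  error = function(e) e)
  if (inherits(out, "error")) {
    expect_match(conditionMessage(out), "higher `fdr`")
  } else {
    at <- out$table[out$table$height == out$height_cutoff, ]
    expect_lt(at$background_count / max(at$chip_count, 1), 2)
  }
})

test_that("swapping identical tag sets calls essentially nothing", {
  sim <- simulate_experiment(sim_preset("null", seed = 56))
  out <- tryCatch(
    call_peaks(sim$input, sim$input,
               peak_call_config(mode = "broad", fdr = 0.01, seed = 56),
               chrom_sizes = c(sim1 = 2e6)),
    error = function(e) e
  )
  if (inherits(out, "error")) {
    expect_match(conditionMessage(out), "no significant enrichment|higher")
  } else {
    expect_lte(nrow(tidy(out)), 1)
  }
})

test_that("broad regions contain the narrow regions on the same data", {
  starts <- seq(2e5, 2.7e6, by = 5e5)
  sim <- simulate_experiment(sim_config(
    chrom_sizes = c(simA = 3e6),
    planted_regions = tibble::tibble(chrom = "simA", start = starts,
                                     end = starts + 3e4,
                                     fold = 8, profile = "jagged"),
    n_chip_tags = 3e5, n_input_tags = 3e5, seed = 57
  ))
  broad <- call_peaks(sim$chip, sim$input,
                      peak_call_config(mode = "broad", fdr = 0.05, seed = 57),
                      chrom_sizes = c(simA = 3e6))
  narrow <- call_peaks(sim$chip, sim$input,
                       peak_call_config(mode = "narrow", fdr = 0.05, seed = 57),
                       chrom_sizes = c(simA = 3e6))
  nb <- tidy(narrow)
  bb <- tidy(broad)
  expect_gt(nrow(nb), 0)
  expect_true(all(bf_has_hit(nb, bb, 1)))
  expect_gt(sum(bb$end - bb$start), sum(nb$end - nb$start))
})

test_that("peak calling is deterministic given the seed", {
  sim <- planted_block_sim(58)
  cfg <- peak_call_config(mode = "narrow", fdr = 0.2, seed = 58)
  a <- call_peaks(sim$chip, sim$input, cfg, chrom_sizes = c(simA = 1e6))
  b <- call_peaks(sim$chip, sim$input, cfg, chrom_sizes = c(simA = 1e6))
  expect_identical(tidy(a), tidy(b))
  expect_identical(tidy(a$calibration), tidy(b$calibration))
})
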