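test_that("bins tile each chromosome and sites land in the right bin", {
  s <- toy_sample(data.frame(
    chrom = "chr1", pos = c(50L, 51L), strand = "+", context = "CG",
    n_meth = c(3L, 1L), n_total = c(5L, 5L)))
  b <- bin_methylome(s, c(chr1 = 120L))
  expect_equal(b$start, c(0L, 50L, 100L))
  expect_equal(b$end, c(50L, 100L, 120L))   # terminal bin shorter
  # 1-based pos 50 is 0-based coordinate 49 -> bin [0,50)
  expect_equal(b$n_total, c(5L, 5L, 0L))
  expect_true(is.na(b$level[3]))            # empty bin retained, untestable
})

test_that("the bin exact test matches enumeration on worked tables", {
  expect_equal(fisher_p(5, 5, 5, 5), 1)
  expect_equal(fisher_p(0, 10, 10, 0), 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_p(1, 0, 0, 1), 1)     # both extreme tables prob 0.5
  tab <- fisher_bin_test(data.frame(
    chrom = "chr1", start = 0L, end = 50L,
    meth_wt = 0L, total_wt = 10L, meth_mut = 10L, total_mut = 10L,
    level_wt = 0, level_mut = 1))
  expect_equal(tab$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(tab$direction, "hyper")
  expect_equal(tab$delta, 1)
})

test_that("the bin exact test agrees with stats::fisher.test on random tables", {
  set.seed(100)
  for (i in 1:200) {
    t <- rpois(4, sample(c(2, 10, 40), 1))
    ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(fisher_p(t[1], t[2], t[3], t[4]), ref, tolerance = 1e-9)
  }
})

test_that("bins with no coverage in one genotype are untestable", {
  tab <- fisher_bin_test(data.frame(
    chrom = "chr1", start = 0L, end = 50L,
    meth_wt = 0L, total_wt = 0L, meth_mut = 5L, total_mut = 10L,
    level_wt = NA_real_, level_mut = 0.5))
  expect_true(is.na(tab$p_value))
  expect_equal(tab$direction, "none")
})

test_that("gap <= 50 merges significant bins, gap 51+ does not", {
  one <- merge_significant_bins(data.frame(
    chrom = "chr1", start = c(0L, 100L), end = c(50L, 150L)), 50L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 0L)
  expect_equal(one$end, 150L)
  two <- merge_significant_bins(data.frame(
    chrom = "chr1", start = c(0L, 150L), end = c(50L, 200L)), 50L)
  expect_equal(nrow(two), 2L)
  # gap 51: just over the boundary
  g51 <- merge_significant_bins(data.frame(
    chrom = "chr1", start = c(0L, 101L), end = c(50L, 151L)), 50L)
  expect_equal(nrow(g51), 2L)
})

test_that("merging is idempotent and independent of input order", {
  set.seed(17)
  starts <- sort(sample(seq(0L, 5000L, by = 50L), 40L))
  bins <- data.frame(chrom = sample(c("c1", "c2"), 40L, TRUE),
                     start = starts, end = starts + 50L)
  m1 <- merge_significant_bins(bins, 50L)
  m2 <- merge_significant_bins(bins[sample.int(nrow(bins)), ], 50L)
  expect_equal(m1[, c("chrom", "start", "end", "n_bins")],
               m2[, c("chrom", "start", "end", "n_bins")])
  again <- merge_significant_bins(m1, 50L)
  expect_equal(again$start, m1$start)
  expect_equal(again$end, m1$end)
})

test_that("stricter alpha or min_delta never yields more DMRs", {
  cfg <- simulation_config(chrom_lengths = c(chr1 = 100000L), seed = 19L,
                           n_dmrs = 8L)
  st <- simulate_methylome_study(cfg)
  lens <- genome_lengths(st$genome)
  n_called <- function(alpha, min_delta) {
    nrow(call_dmrs(st$wt, st$mut, lens,
                   dmr_params(alpha = alpha, min_delta = min_delta)))
  }
  expect_gte(n_called(0.01, 0.1), n_called(0.001, 0.1))
  expect_gte(n_called(0.01, 0.1), n_called(0.01, 0.3))
})

test_that("planted hyper-DMRs are each intersected by a called DMR", {
  cfg <- simulation_config(
    chrom_lengths = c(chr1 = 150000L), seed = 23L, n_dmrs = 6L,
    dmr_width = c(400L, 400L),
    dmr_delta = c(CG = 0.6, CHG = 0.6, CHH = 0.6))
  st <- simulate_methylome_study(cfg)
  dmrs <- call_dmrs(st$wt, st$mut, genome_lengths(st$genome))
  called <- dmr_granges(dmrs)
  hit <- GenomicRanges::countOverlaps(st$planted, called,
                                      ignore.strand = TRUE)
  expect_true(all(hit >= 1))
  expect_true(all(dmrs$direction == "hyper"))
  expect_true(all(dmrs$end - dmrs$start >= 50))
})

test_that("mismatched chromosome sets are fatal and DMR output is coordinate-sorted", {
  s1 <- toy_sample(data.frame(chrom = "chr1", pos = 10L, strand = "+",
                              context = "CG", n_meth = 5L, n_total = 5L))
  s2 <- toy_sample(data.frame(chrom = "chrX", pos = 10L, strand = "+",
                              context = "CG", n_meth = 0L, n_total = 5L))
  expect_error(bin_table(s1, s2, c(chr1 = 100L)), "missing from")
})

test_that("DMR BED export round-trips coordinates", {
  cfg <- simulation_config(chrom_lengths = c(chr1 = 80000L), seed = 29L,
                           n_dmrs = 4L)
  st <- simulate_methylome_study(cfg)
  dmrs <- call_dmrs(st$wt, st$mut, genome_lengths(st$genome))
  f <- tempfile(fileext = ".bed")
  write_dmr_bed(dmrs, f)
  back <- read_bed(f)
  expect_equal(GenomicRanges::start(back) - 1L, dmrs$start)
  expect_equal(GenomicRanges::end(back), dmrs$end)
})
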