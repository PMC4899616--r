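test_that("genome simulation is reproducible and respects GC limits", {
  cfg <- simulation_config(chrom_lengths = c(chr1 = 10000L), seed = 5L,
                           n_dmrs = 4L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(unclass(a$genome), unclass(b$genome))
  expect_identical(as.data.frame(a$planted), as.data.frame(b$planted))

  gc1 <- simulate_genome(simulation_config(chrom_lengths = c(c1 = 2000L),
                                           gc = 1, n_dmrs = 0L, seed = 2L))
  expect_true(grepl("^[GC]+$", unclass(gc1$genome)[["c1"]]))

  expect_error(simulation_config(te_fraction = 0.6, gene_fraction = 0.6),
               "must be <= 1")
})

test_that("class map tiles the genome and TE coverage tracks the requested fraction", {
  cfg <- simulation_config(chrom_lengths = c(chr1 = 200000L),
                           te_fraction = 0.3, gene_fraction = 0.5,
                           n_dmrs = 0L, seed = 9L)
  g <- simulate_genome(cfg)
  w <- sum(GenomicRanges::width(GenomicRanges::reduce(g$classmap)))
  expect_equal(w, 200000L)  # full coverage, no gaps
  te_w <- sum(GenomicRanges::width(
    g$classmap[S4Vectors::mcols(g$classmap)$class == "TE"]))
  expect_gt(te_w / 200000, 0.3 - 0.12)
  expect_lt(te_w / 200000, 0.3 + 0.12)
})

test_that("count simulation is reproducible and follows the binomial model", {
  cfg <- simulation_config(chrom_lengths = c(chr1 = 30000L), seed = 21L,
                           n_dmrs = 2L, dmr_width = c(400L, 400L))
  g <- simulate_genome(cfg)
  s1 <- simulate_counts(g$genome, g$classmap, cfg, g$planted)
  s2 <- simulate_counts(g$genome, g$classmap, cfg, g$planted)
  expect_identical(as.data.frame(s1$wt), as.data.frame(s2$wt))
  expect_identical(as.data.frame(s1$mut), as.data.frame(s2$mut))

  # degenerate: m = 1 everywhere, fixed depth 10 => every site 10/10
  cfg1 <- simulation_config(
    chrom_lengths = c(chr1 = 3000L), n_dmrs = 0L, seed = 3L,
    mean_depth = 10, fixed_depth = TRUE,
    profile = methylation_profile(TE = c(CG = 1, CHG = 1, CHH = 1),
                                  gene = c(CG = 1, CHG = 1, CHH = 1),
                                  intergenic = c(CG = 1, CHG = 1, CHH = 1)))
  g1 <- simulate_genome(cfg1)
  s <- simulate_counts(g1$genome, g1$classmap, cfg1)
  expect_true(all(s$wt$n_total == 10L))
  expect_true(all(s$wt$n_meth == 10L))
})

test_that("mean mutant methylation inside a planted region matches baseline + delta", {
  # CG baseline 0.1 everywhere, planted [1001, 1400] with delta_CG 0.6
  prof <- methylation_profile(TE = c(CG = .1, CHG = .1, CHH = .1),
                              gene = c(CG = .1, CHG = .1, CHH = .1),
                              intergenic = c(CG = .1, CHG = .1, CHH = .1))
  cfg <- simulation_config(chrom_lengths = c(chr1 = 5000L), profile = prof,
                           mean_depth = 20, n_dmrs = 0L, seed = 13L)
  g <- simulate_genome(cfg)
  planted <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1400))
  S4Vectors::mcols(planted)$delta_CG <- 0.6
  S4Vectors::mcols(planted)$delta_CHG <- 0.6
  S4Vectors::mcols(planted)$delta_CHH <- 0.6
  s <- simulate_counts(g$genome, g$classmap, cfg, planted)
  inside <- s$mut[s$mut$pos >= 1001 & s$mut$pos <= 1400 &
                    s$mut$context == "CG", ]
  lvl <- sum(inside$n_meth) / sum(inside$n_total)
  se <- sqrt(0.7 * 0.3 / sum(inside$n_total))
  expect_lt(abs(lvl - 0.7), 3 * se)
})

test_that("empirical site-level methylation converges to the configured value at high depth", {
  prof <- methylation_profile(TE = c(CG = .8, CHG = .6, CHH = .15),
                              gene = c(CG = .05, CHG = .02, CHH = .02),
                              intergenic = c(CG = .1, CHG = .05, CHH = .03))
  cfg <- simulation_config(chrom_lengths = c(chr1 = 50000L), profile = prof,
                           mean_depth = 200, n_dmrs = 0L, seed = 31L)
  g <- simulate_genome(cfg)
  s <- simulate_counts(g$genome, g$classmap, cfg)
  ann <- classmap_annotation(g$classmap)
  # pooled CG level across TE blocks should sit at the configured 0.8
  rmeth <- region_methylation(s$wt, ann$tes, min_cov = 3)
  cg <- rmeth[rmeth$context == "CG" & rmeth$n_total > 0, ]
  pooled <- sum(cg$n_meth) / sum(cg$n_total)
  expect_lt(abs(pooled - 0.8), 0.02)
  gn <- region_methylation(s$wt, ann$genes, min_cov = 3)
  cgg <- gn[gn$context == "CG" & gn$n_total > 0, ]
  expect_lt(abs(sum(cgg$n_meth) / sum(cgg$n_total) - 0.05), 0.02)
})

test_that("cytosine reports round-trip byte-identically for a fixed config", {
  cfg <- simulation_config(chrom_lengths = c(chr1 = 20000L), seed = 77L,
                           n_dmrs = 2L)
  st <- simulate_methylome_study(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_cx_report(st$wt, f1)
  st2 <- simulate_methylome_study(cfg)
  write_cx_report(st2$wt, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_cytosine_report(f1, label = "wt")
  expect_equal(back$n_meth, st$wt$n_meth)
  expect_equal(back$n_total, st$wt$n_total)
  expect_equal(back$context, st$wt$context)
})
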