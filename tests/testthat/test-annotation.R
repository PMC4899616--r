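test_that("GFF3 and BED annotations load genes and TEs", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttair\tgene\t1001\t3000\t.\t+\t.\tID=gene1",
    "chr1\ttair\tgene\t5001\t6000\t.\t-\t.\tID=gene2",
    "chr1\ttair\ttransposable_element\t4001\t4500\t.\t.\t.\tID=te1",
    "chr1\ttair\texon\t1001\t1500\t.\t+\t.\tParent=gene1"), gff)
  ann <- read_annotation(gff)
  expect_equal(length(ann$genes), 2L)
  expect_equal(length(ann$tes), 1L)
  expect_equal(as.character(GenomicRanges::strand(ann$genes)), c("+", "-"))
  expect_equal(GenomicRanges::start(ann$tes), 4001L)

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t3000\tgene\t0\t+",
               "chr1\t4000\t4500\tTE\t0\t."), bed)
  ann2 <- read_annotation(bed)
  expect_equal(GenomicRanges::start(ann2$genes), 1001L)
  expect_equal(length(ann2$tes), 1L)
})

test_that("DMR composition assigns one category by priority and sums to 100%", {
  ann <- feature_annotation(
    genes = GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 3000),
                                   strand = "+"),
    tes = GenomicRanges::GRanges("chr1", IRanges::IRanges(2500, 4500)))
  dmrs <- data.frame(chrom = "chr1",
                     start = c(2600L, 4000L, 9000L),  # gene+TE, TE, nothing
                     end = c(2700L, 4100L, 9100L))
  comp <- classify_dmrs(dmrs, ann)
  expect_equal(comp$assignment, c("genic", "TE", "intergenic"))
  expect_equal(sum(comp$table$n), 3L)
  expect_equal(sum(comp$table$pct), 100)
  # TE-first priority flips the shared DMR
  comp2 <- classify_dmrs(dmrs, ann, priority = c("TE", "genic", "intergenic"))
  expect_equal(comp2$assignment[1], "TE")
  # empty set
  empty <- classify_dmrs(data.frame(chrom = character(), start = integer(),
                                    end = integer()), ann)
  expect_equal(empty$n_dmrs, 0L)
  expect_true(all(is.na(empty$table$pct)))
})

test_that("a planted composition is recovered by the classifier", {
  cfg <- simulation_config(chrom_lengths = c(chr1 = 400000L), seed = 37L,
                           n_dmrs = 30L,
                           dmr_classes = c(gene = 0.7, intergenic = 0.3))
  g <- simulate_genome(cfg)
  ann <- classmap_annotation(g$classmap)
  comp <- classify_dmrs(g$planted, ann)
  genic_pct <- comp$table[comp$table$category == "genic", ]$pct
  expect_gt(genic_pct, 50)   # ~70% planted in genes, binomial spread at n=30
})

test_that("a spatially constant methylation field gives a flat metaprofile", {
  prof <- methylation_profile(TE = c(CG = .5, CHG = .5, CHH = .5),
                              gene = c(CG = .5, CHG = .5, CHH = .5),
                              intergenic = c(CG = .5, CHG = .5, CHH = .5))
  cfg <- simulation_config(chrom_lengths = c(chr1 = 120000L), profile = prof,
                           mean_depth = 20, fixed_depth = TRUE,
                           n_dmrs = 0L, seed = 43L)
  g <- simulate_genome(cfg)
  s <- simulate_counts(g$genome, g$classmap, cfg)
  genes <- classmap_annotation(g$classmap)$genes
  mp <- gene_metaprofile(s$wt, genes)
  occ <- mp$total > 0
  expect_true(all(abs(mp$profile[occ] - 0.5) < 0.05))
})

test_that("minus-strand genes are orientation-flipped so upstream is left", {
  # methylation only 5' of the TSS of a minus-strand gene (i.e. at
  # coordinates above the gene end) must land in upstream (left) bins
  g <- as_genome(c(chr1 = paste(rep("ACGTA", 2000), each = 1,
                                collapse = "")))
  calls <- enumerate_cytosines(g)
  calls <- calls[calls$context != "ambiguous"]
  gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4001, 6000),
                                 strand = "-")
  upstream <- calls$pos > 6000 & calls$pos <= 7000
  s <- methylome(data.frame(
    chrom = "chr1", pos = calls$pos, strand = calls$strand,
    context = calls$context,
    n_meth = ifelse(upstream, 10L, 0L), n_total = 10L), "flip")
  mp <- gene_metaprofile(s, gene)
  up_cols <- grep("^up_", mp$bins)
  body_cols <- grep("^body_", mp$bins)
  expect_true(all(mp$profile[, up_cols][mp$total[, up_cols] > 0] == 1))
  expect_true(all(mp$profile[, body_cols][mp$total[, body_cols] > 0] == 0))
})

test_that("the metaprofile is invariant under reverse-complementing everything", {
  cfg <- simulation_config(chrom_lengths = c(chr1 = 60000L), seed = 47L,
                           n_dmrs = 0L)
  g <- simulate_genome(cfg)
  s <- simulate_counts(g$genome, g$classmap, cfg)
  genes <- classmap_annotation(g$classmap)$genes
  L <- genome_lengths(g$genome)[["chr1"]]
  mp <- gene_metaprofile(s$wt, genes)

  flip_sample <- methylome(data.frame(
    chrom = "chr1", pos = L - s$wt$pos + 1L,
    strand = ifelse(s$wt$strand == "+", "-", "+"),
    context = s$wt$context, n_meth = s$wt$n_meth,
    n_total = s$wt$n_total), "rc")
  flip_genes <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(L - GenomicRanges::end(genes) + 1L,
                     L - GenomicRanges::start(genes) + 1L),
    strand = ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                    "-", "+"))
  mp2 <- gene_metaprofile(flip_sample, flip_genes)
  expect_equal(mp2$meth, mp$meth)
  expect_equal(mp2$total, mp$total)
})

test_that("TE-flanked genes show flank-elevated methylation profiles", {
  # deterministic geometry: gene bodies flanked by TE blocks on both sides
  cfg <- simulation_config(chrom_lengths = c(chr1 = 100000L), seed = 53L,
                           n_dmrs = 0L, mean_depth = 20)
  g <- simulate_genome(cfg)
  blocks <- list()
  at <- 1L
  while (at + 4000L <= 100000L) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      start = c(at, at + 1000L, at + 3000L),
      end = c(at + 999L, at + 2999L, at + 3999L),
      class = c("TE", "gene", "TE"),
      strand = c("*", sample(c("+", "-"), 1), "*"))
    at <- at + 4000L
  }
  bl <- do.call(rbind, blocks)
  classmap <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(bl$start, bl$end),
                                     strand = bl$strand)
  S4Vectors::mcols(classmap)$class <- bl$class
  s <- simulate_counts(g$genome, classmap, cfg)
  genes <- classmap_annotation(classmap)$genes
  mp <- gene_metaprofile(s$wt, genes)
  cg <- mp$profile["CG", ]
  flanks <- mean(cg[grep("^(up|down)_", mp$bins)], na.rm = TRUE)
  body <- mean(cg[grep("^body_", mp$bins)], na.rm = TRUE)
  expect_gt(flanks, body + 0.3)   # TE flanks are heavily CG-methylated
})
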