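# Synthetic paired methylomes with planted hyper-DMRs.
#
# The generator emulates a plant (Arabidopsis-like) methylome: a random
# genome tiled with TE / gene / intergenic blocks, context- and
# class-dependent baseline methylation (TEs high CG/CHG, genes low),
# per-site read depth (Poisson or fixed) and binomial methylated counts.
# The mutant adds a per-context methylation increment inside planted
# regions, giving ground truth for the DMR caller.

#' Baseline methylation profile per region class and context
#'
#' Defaults emulate a plant methylome: TEs heavily methylated at CG/CHG
#' with moderate CHH, genes nearly unmethylated, intergenic background
#' low.
#'
#' @param TE,gene,intergenic Named numeric vectors with entries `CG`,
#'   `CHG`, `CHH`, all in `[0, 1]`.
#' @return Matrix (class x context) of class `methylation_profile`.
#' @export
methylation_profile <- function(
    TE = c(CG = 0.80, CHG = 0.60, CHH = 0.15),
    gene = c(CG = 0.05, CHG = 0.02, CHH = 0.02),
    intergenic = c(CG = 0.10, CHG = 0.05, CHH = 0.03)) {
  m <- rbind(TE = TE[c("CG", "CHG", "CHH")],
             gene = gene[c("CG", "CHG", "CHH")],
             intergenic = intergenic[c("CG", "CHG", "CHH")])
  colnames(m) <- c("CG", "CHG", "CHH")
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    stop("all baseline methylation probabilities must be in [0, 1]")
  }
  structure(m, class = c("methylation_profile", class(m)))
}

#' Simulation configuration
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param gc GC fraction of the simulated genome (default 0.36,
#'   Arabidopsis-like).
#' @param te_fraction,gene_fraction Target genome fractions of TE and gene
#'   blocks (the rest is intergenic); must sum to < 1.
#' @param mean_te_length,mean_gene_length,mean_intergenic_length Mean
#'   block lengths in bp.
#' @param profile A [methylation_profile()].
#' @param mean_depth Mean per-site read depth (Poisson lambda), > 0.
#' @param fixed_depth If `TRUE`, every site gets exactly `mean_depth`
#'   reads (makes count-based oracles exact).
#' @param paired_depth If `TRUE`, wild type and mutant share the same
#'   depth draws.
#' @param n_dmrs Number of hyper-DMRs to plant (default 80 on the default
#'   2-Mb genome).
#' @param dmr_width Width range (bp) of planted DMRs, drawn uniformly
#'   (default 200-1000).
#' @param dmr_delta Named per-context methylation increments applied in
#'   the mutant inside planted regions (clipped to 1).
#' @param dmr_classes Probabilities of planting in each region class
#'   (default 70% gene, 30% intergenic, mirroring the predominantly genic
#'   location of demethylation-target hyper-DMRs).
#' @param hypo If `TRUE` the increments are subtracted instead (off by
#'   default; the pipeline's focus is hypermethylation).
#' @param seed Integer seed fixing the whole output stream.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(chrom_lengths = c(chr1 = 2e6),
                              gc = 0.36,
                              te_fraction = 0.15, gene_fraction = 0.50,
                              mean_te_length = 2000,
                              mean_gene_length = 2500,
                              mean_intergenic_length = 1500,
                              profile = methylation_profile(),
                              mean_depth = 20, fixed_depth = FALSE,
                              paired_depth = FALSE,
                              n_dmrs = 80L,
                              dmr_width = c(200L, 1000L),
                              dmr_delta = c(CG = 0.5, CHG = 0.5, CHH = 0.3),
                              dmr_classes = c(gene = 0.7, intergenic = 0.3),
                              hypo = FALSE,
                              seed = 1L) {
  if (te_fraction + gene_fraction > 1) {
    stop("te_fraction + gene_fraction must be <= 1")
  }
  stopifnot(gc >= 0, gc <= 1, mean_depth > 0, n_dmrs >= 0,
            length(dmr_width) == 2L, dmr_width[1L] >= 50L,
            dmr_width[2L] >= dmr_width[1L],
            all(dmr_delta >= 0), all(dmr_delta <= 1))
  structure(list(chrom_lengths = chrom_lengths, gc = gc,
                 te_fraction = te_fraction, gene_fraction = gene_fraction,
                 mean_te_length = mean_te_length,
                 mean_gene_length = mean_gene_length,
                 mean_intergenic_length = mean_intergenic_length,
                 profile = profile, mean_depth = mean_depth,
                 fixed_depth = fixed_depth, paired_depth = paired_depth,
                 n_dmrs = as.integer(n_dmrs),
                 dmr_width = as.integer(dmr_width),
                 dmr_delta = dmr_delta, dmr_classes = dmr_classes,
                 hypo = hypo, seed = as.integer(seed)),
            class = "sim_config")
}

# segment classes are drawn i.i.d. with probabilities proportional to
# fraction / mean_length so the expected length share matches the target
.tile_classes <- function(L, config) {
  fr <- c(TE = config$te_fraction, gene = config$gene_fraction,
          intergenic = 1 - config$te_fraction - config$gene_fraction)
  ml <- c(TE = config$mean_te_length, gene = config$mean_gene_length,
          intergenic = config$mean_intergenic_length)
  pr <- fr / ml
  pr <- pr / sum(pr)
  segs <- list()
  at <- 1L
  while (at <= L) {
    cls <- sample(names(pr), 1L, prob = pr)
    len <- max(100L, as.integer(round(stats::rgamma(1L, shape = 4,
                                                    scale = ml[[cls]] / 4))))
    segs[[length(segs) + 1L]] <- data.table::data.table(
      start = at, end = min(L, at + len - 1L), class = cls)
    at <- at + len
  }
  data.table::rbindlist(segs)
}

#' Simulate a genome, region-class map and planted DMRs
#'
#' Draws a random genome at the configured GC content, tiles it with
#' TE/gene/intergenic blocks, and plants non-overlapping hyper-DMR
#' regions (in gene/intergenic blocks by default, avoiding TEs whose high
#' baseline would clip the increment).
#'
#' @param config A [simulation_config()].
#' @return List: `genome` (a `methdmr_genome`), `classmap` (`GRanges`
#'   tiling each chromosome, metadata `class`; gene blocks carry a
#'   random strand), `planted` (`GRanges` of planted DMRs with the
#'   per-context deltas as metadata).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  base_p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
              G = config$gc / 2, T = (1 - config$gc) / 2)
  seqs <- vapply(config$chrom_lengths, function(L) {
    paste(sample(names(base_p), L, replace = TRUE, prob = base_p),
          collapse = "")
  }, character(1))
  genome <- as_genome(seqs)

  maps <- lapply(names(config$chrom_lengths), function(cn) {
    dt <- .tile_classes(config$chrom_lengths[[cn]], config)
    gr <- GenomicRanges::GRanges(
      seqnames = cn, ranges = IRanges::IRanges(dt$start, dt$end),
      strand = ifelse(dt$class == "gene",
                      sample(c("+", "-"), nrow(dt), replace = TRUE), "*"))
    S4Vectors::mcols(gr)$class <- dt$class
    gr
  })
  classmap <- do.call(c, maps)

  planted <- .plant_dmrs(classmap, config)
  list(genome = genome, classmap = classmap, planted = planted)
}

# place n_dmrs non-overlapping regions inside blocks of the requested
# classes, leaving >= 200 bp between planted regions so merged calls stay
# distinct
.plant_dmrs <- function(classmap, config) {
  empty <- GenomicRanges::GRanges()
  if (config$n_dmrs == 0L) return(empty)
  host_cls <- sample(names(config$dmr_classes), config$n_dmrs,
                     replace = TRUE, prob = config$dmr_classes)
  widths <- as.integer(round(stats::runif(config$n_dmrs,
                                          config$dmr_width[1L],
                                          config$dmr_width[2L])))
  placed <- list()
  occupied <- GenomicRanges::GRanges()
  for (i in seq_len(config$n_dmrs)) {
    hosts <- classmap[S4Vectors::mcols(classmap)$class == host_cls[i] &
                        GenomicRanges::width(classmap) >= widths[i]]
    ok <- FALSE
    for (try in seq_len(50L)) {
      if (!length(hosts)) break
      h <- hosts[sample.int(length(hosts), 1L)]
      lo <- GenomicRanges::start(h)
      hi <- GenomicRanges::end(h) - widths[i] + 1L
      if (hi < lo) next
      s <- as.integer(floor(stats::runif(1L, lo, hi + 1)))
      cand <- GenomicRanges::GRanges(
        seqnames = as.character(GenomicRanges::seqnames(h)),
        ranges = IRanges::IRanges(s, s + widths[i] - 1L))
      pad <- GenomicRanges::resize(cand, GenomicRanges::width(cand) + 400L,
                                   fix = "center")
      if (length(occupied) &&
          length(GenomicRanges::findOverlaps(pad, occupied))) next
      occupied <- c(occupied, cand)
      placed[[length(placed) + 1L]] <- cand
      ok <- TRUE
      break
    }
    # a region that cannot be placed after 50 tries is skipped
  }
  if (!length(placed)) return(empty)
  gr <- GenomicRanges::sort(do.call(c, placed))
  S4Vectors::mcols(gr)$delta_CG <- config$dmr_delta[["CG"]]
  S4Vectors::mcols(gr)$delta_CHG <- config$dmr_delta[["CHG"]]
  S4Vectors::mcols(gr)$delta_CHH <- config$dmr_delta[["CHH"]]
  S4Vectors::mcols(gr)$name <- sprintf("planted_%d", seq_along(gr))
  gr
}

#' Simulate paired wild-type and mutant methylomes
#'
#' One cytosine site per non-ambiguous cytosine per strand. Depth is
#' Poisson(`mean_depth`) (or fixed); methylated counts are binomial at the
#' class/context baseline, with the planted per-context increment applied
#' in the mutant (clipped to `[0, 1]`). Draw order is fixed: all wild-type
#' draws (depths, then methylated counts) precede all mutant draws, sites
#' in coordinate order, so a given config and seed reproduces the output
#' byte-identically.
#'
#' @param genome A `methdmr_genome` (from [simulate_genome()]).
#' @param classmap Region-class `GRanges` (metadata `class`).
#' @param config A [simulation_config()].
#' @param planted `GRanges` of planted DMRs (metadata `delta_CG`,
#'   `delta_CHG`, `delta_CHH`); `NULL` for none.
#' @return List of two [methylome()] samples, `wt` and `mut`.
#' @export
simulate_counts <- function(genome, classmap, config, planted = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  sites <- enumerate_cytosines(genome)[context != "ambiguous"]

  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, sites$pos))
  cls <- rep("intergenic", nrow(sites))
  hit <- GenomicRanges::findOverlaps(sgr, classmap, select = "first",
                                     ignore.strand = TRUE)
  has <- !is.na(hit)
  cls[has] <- S4Vectors::mcols(classmap)$class[hit[has]]

  prof <- config$profile
  m_wt <- prof[cbind(match(cls, rownames(prof)),
                     match(sites$context, colnames(prof)))]
  m_mut <- m_wt
  if (!is.null(planted) && length(planted)) {
    ph <- GenomicRanges::findOverlaps(sgr, planted, select = "first",
                                      ignore.strand = TRUE)
    inp <- !is.na(ph)
    dl <- cbind(S4Vectors::mcols(planted)$delta_CG,
                S4Vectors::mcols(planted)$delta_CHG,
                S4Vectors::mcols(planted)$delta_CHH)
    dsite <- dl[cbind(ph[inp], match(sites$context[inp],
                                     c("CG", "CHG", "CHH")))]
    m_mut[inp] <- if (config$hypo) pmax(0, m_mut[inp] - dsite)
                  else pmin(1, m_mut[inp] + dsite)
  }

  n <- nrow(sites)
  draw_depth <- function() {
    if (config$fixed_depth) rep(as.integer(config$mean_depth), n)
    else stats::rpois(n, config$mean_depth)
  }
  d_wt <- draw_depth()
  meth_wt <- stats::rbinom(n, d_wt, m_wt)
  d_mut <- if (config$paired_depth) d_wt else draw_depth()
  meth_mut <- stats::rbinom(n, d_mut, m_mut)

  mk <- function(dep, met, label) {
    methylome(data.table::data.table(
      chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
      context = sites$context, n_meth = met, n_total = dep,
      tri = sites$tri), label = label)
  }
  list(wt = mk(d_wt, meth_wt, "wt"), mut = mk(d_mut, meth_mut, "mut"))
}

#' Simulate a full study (genome, classmap, planted truth, two samples)
#'
#' Convenience wrapper running [simulate_genome()] then
#' [simulate_counts()].
#'
#' @param config A [simulation_config()].
#' @return List: `genome`, `classmap`, `planted`, `wt`, `mut`, `config`.
#' @export
simulate_methylome_study <- function(config = simulation_config()) {
  g <- simulate_genome(config)
  s <- simulate_counts(g$genome, g$classmap, config, g$planted)
  c(g, s, list(config = config))
}

#' Genes and TEs of a simulated class map
#'
#' @param classmap `GRanges` from [simulate_genome()].
#' @return A [feature_annotation()] with the gene blocks (stranded) and
#'   TE blocks.
#' @export
classmap_annotation <- function(classmap) {
  cls <- S4Vectors::mcols(classmap)$class
  feature_annotation(genes = classmap[cls == "gene"],
                     tes = classmap[cls == "TE"])
}
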