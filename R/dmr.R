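# Bin-based hyper-DMR caller.
#
# The genome is tiled with fixed-width bins (50 bp). Within each bin,
# coverage-passing cytosine counts are pooled per genotype (all contexts
# by default) and compared with a two-sided Fisher exact test. Bins that
# reach significance and effect size in the requested direction are merged
# into DMRs whenever the gap to the next significant bin is at most
# merge_gap (50 bp, i.e. at most one intervening non-significant bin).

#' Parameters for DMR calling
#'
#' @param bin_size Bin width in bp (default 50).
#' @param merge_gap Maximum gap between significant bins that still merges
#'   them into one DMR (default 50 bp).
#' @param min_cov Per-site coverage filter (default 3).
#' @param alpha Per-bin p-value cutoff (default 0.01). No multiple-testing
#'   correction is applied by default; set `fdr = TRUE` for BH-adjusted
#'   cutoffs.
#' @param min_delta Minimum absolute methylation-level difference
#'   (mutant - wild type) for a significant bin (default 0.1).
#' @param min_total Minimum pooled read count per bin per sample for the
#'   bin to be testable (default 1).
#' @param direction `"hyper"` (default: mutant above wild type), `"hypo"`,
#'   or `"both"`.
#' @param context `"all"` (pool every context, default) or one of `CG`,
#'   `CHG`, `CHH` to restrict the test to a context.
#' @param fdr Apply Benjamini-Hochberg correction to bin p-values before
#'   the `alpha` cutoff (default `FALSE`).
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(bin_size = 50L, merge_gap = 50L, min_cov = 3L,
                       alpha = 0.01, min_delta = 0.1, min_total = 1L,
                       direction = c("hyper", "hypo", "both"),
                       context = c("all", "CG", "CHG", "CHH"),
                       fdr = FALSE) {
  direction <- match.arg(direction)
  context <- match.arg(context)
  stopifnot(bin_size >= 1, merge_gap >= 0, min_cov >= 1,
            alpha > 0, alpha < 1, min_delta >= 0, min_total >= 1)
  structure(list(bin_size = as.integer(bin_size),
                 merge_gap = as.integer(merge_gap),
                 min_cov = as.integer(min_cov), alpha = alpha,
                 min_delta = min_delta, min_total = as.integer(min_total),
                 direction = direction, context = context, fdr = fdr),
            class = "dmr_params")
}

#' Two-sided Fisher exact test p-values for 2x2 count tables
#'
#' Vectorised exact test on tables
#' `[[meth_a, unmeth_a], [meth_b, unmeth_b]]`. The two-sided p-value is
#' the sum, over all tables with the observed margins, of hypergeometric
#' probabilities not exceeding that of the observed table (with the
#' standard relative tolerance `1 + 1e-7` for ties).
#'
#' @param meth_a,unmeth_a,meth_b,unmeth_b Non-negative integer vectors.
#' @return Numeric vector of p-values in (0, 1].
#' @export
fisher_p <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  n <- length(meth_a)
  stopifnot(length(unmeth_a) == n, length(meth_b) == n, length(unmeth_b) == n)
  if (any(c(meth_a, unmeth_a, meth_b, unmeth_b) < 0)) {
    stop("counts must be non-negative")
  }
  ra <- meth_a + unmeth_a
  rb <- meth_b + unmeth_b
  k <- meth_a + meth_b
  vapply(seq_len(n), function(i) {
    lo <- max(0L, k[i] - rb[i])
    hi <- min(k[i], ra[i])
    d <- stats::dhyper(lo:hi, ra[i], rb[i], k[i])
    sum(d[d <= d[meth_a[i] - lo + 1L] * (1 + 1e-7)])
  }, numeric(1))
}

#' Pool a methylome into fixed-width genomic bins
#'
#' Tiles each chromosome from coordinate 0 with `bin_size`-wide bins (the
#' last bin may be shorter) and pools methylated/total counts of
#' coverage-passing cytosines into them. A cytosine at 1-based position p
#' falls in the bin containing 0-based coordinate p-1.
#'
#' @param sample A [methylome()] sample.
#' @param chrom_lengths Named vector of chromosome lengths (e.g.
#'   [genome_lengths()]); inferred from the sample's maximal positions if
#'   `NULL`.
#' @param params A [dmr_params()] object.
#' @return `data.table` with one row per bin: `chrom`, `start`, `end`
#'   (0-based half-open), `n_meth`, `n_total`, `level` (`NA` when no
#'   passing reads). Empty bins are retained.
#' @export
bin_methylome <- function(sample, chrom_lengths = NULL,
                          params = dmr_params()) {
  if (is.null(chrom_lengths)) {
    ml <- sample[, .(len = max(pos)), by = chrom]
    chrom_lengths <- stats::setNames(ml$len, ml$chrom)
  }
  bs <- params$bin_size
  tiles <- data.table::rbindlist(lapply(names(chrom_lengths), function(cn) {
    L <- chrom_lengths[[cn]]
    starts <- seq.int(0L, max(0L, L - 1L), by = bs)
    data.table::data.table(chrom = cn, start = starts,
                           end = pmin(starts + bs, L))
  }))
  use <- sample[site_passes_coverage(sample, params$min_cov)]
  if (params$context != "all") use <- use[context == params$context]
  if (nrow(use)) {
    use <- use[chrom %in% names(chrom_lengths)]
    agg <- use[, .(n_meth = sum(n_meth), n_total = sum(n_total)),
               by = .(chrom, start = ((pos - 1L) %/% bs) * bs)]
    out <- merge(tiles, agg, by = c("chrom", "start"), all.x = TRUE)
  } else {
    out <- data.table::copy(tiles)
    out[, `:=`(n_meth = NA_integer_, n_total = NA_integer_)]
  }
  out[is.na(n_total), `:=`(n_meth = 0L, n_total = 0L)]
  out[, level := ifelse(n_total > 0, n_meth / n_total, NA_real_)]
  data.table::setorderv(out, c("chrom", "start"))
  out[]
}

#' Per-bin count table for two genotypes
#'
#' Runs [bin_methylome()] on both samples over a common tiling and joins
#' the per-bin counts.
#'
#' @param wt,mut [methylome()] samples (wild type, mutant).
#' @inheritParams bin_methylome
#' @return `data.table`: `chrom`, `start`, `end`, `meth_wt`, `total_wt`,
#'   `meth_mut`, `total_mut`, `level_wt`, `level_mut`.
#' @export
bin_table <- function(wt, mut, chrom_lengths = NULL, params = dmr_params()) {
  if (is.null(chrom_lengths)) {
    both <- data.table::rbindlist(list(
      wt[, .(chrom, pos)], mut[, .(chrom, pos)]))
    ml <- both[, .(len = max(pos)), by = chrom]
    chrom_lengths <- stats::setNames(ml$len, ml$chrom)
  } else {
    cw <- unique(wt$chrom); cm <- unique(mut$chrom)
    extra <- setdiff(union(cw, cm), names(chrom_lengths))
    if (length(extra)) {
      stop("sample chromosomes missing from chrom_lengths: ",
           paste(extra, collapse = ", "))
    }
  }
  bw <- bin_methylome(wt, chrom_lengths, params)
  bm <- bin_methylome(mut, chrom_lengths, params)
  out <- bw[, .(chrom, start, end, meth_wt = n_meth, total_wt = n_total,
                level_wt = level)]
  out[, `:=`(meth_mut = bm$n_meth, total_mut = bm$n_total,
             level_mut = bm$level)]
  data.table::setcolorder(out, c("chrom", "start", "end", "meth_wt",
                                 "total_wt", "meth_mut", "total_mut",
                                 "level_wt", "level_mut"))
  out[]
}

#' Fisher exact test on binned counts
#'
#' Tests each bin's pooled 2x2 table
#' `[[meth_wt, unmeth_wt], [meth_mut, unmeth_mut]]` with the two-sided
#' exact test. Bins with fewer than `min_total` pooled reads in either
#' sample are untestable: `p_value = NA`, `direction = "none"`.
#'
#' @param bins Output of [bin_table()].
#' @param params A [dmr_params()] object.
#' @return The input with added columns `p_value`, `delta`
#'   (`level_mut - level_wt`) and `direction` (`hyper`/`hypo`/`none`).
#' @export
fisher_bin_test <- function(bins, params = dmr_params()) {
  out <- data.table::copy(data.table::as.data.table(bins))
  testable <- out$total_wt >= params$min_total &
    out$total_mut >= params$min_total
  out[, `:=`(p_value = NA_real_, delta = NA_real_, direction = "none")]
  if (any(testable)) {
    t <- out[testable]
    p <- fisher_p(t$meth_wt, t$total_wt - t$meth_wt,
                  t$meth_mut, t$total_mut - t$meth_mut)
    d <- t$meth_mut / t$total_mut - t$meth_wt / t$total_wt
    out[testable, `:=`(
      p_value = p, delta = d,
      direction = data.table::fcase(d > 0, "hyper", d < 0, "hypo",
                                    default = "none")
    )]
  }
  out[]
}

#' Merge significant bins into regions
#'
#' Merges same-chromosome intervals left-to-right whenever the gap to the
#' next interval (`next start - current end`, 0-based half-open) is at
#' most `merge_gap`. Merging is idempotent and does not depend on the
#' input row order.
#'
#' @param bins data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param merge_gap Maximum gap in bp (default 50).
#' @return `data.table`: `chrom`, `start`, `end`, `n_bins` (members
#'   merged), `member_first`, `member_last` (row indices into the sorted
#'   input).
#' @export
merge_significant_bins <- function(bins, merge_gap = 50L) {
  dt <- data.table::as.data.table(bins)[, .(chrom, start, end)]
  data.table::setorderv(dt, c("chrom", "start"))
  if (!nrow(dt)) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_bins = integer(),
                                  member_first = integer(),
                                  member_last = integer()))
  }
  new_grp <- c(TRUE, dt$chrom[-1L] != dt$chrom[-nrow(dt)] |
                 dt$start[-1L] - cummax_by_chrom(dt) > merge_gap)
  dt[, grp := cumsum(new_grp)]
  dt[, row := .I]
  dt[, .(chrom = chrom[1L], start = min(start), end = max(end),
         n_bins = .N, member_first = min(row), member_last = max(row)),
     by = grp][, grp := NULL][]
}

# running max of `end` within the previous rows of each chromosome,
# aligned so element i is the max end among rows 1..i-1 of the same chrom
cummax_by_chrom <- function(dt) {
  ends <- stats::ave(dt$end, dt$chrom, FUN = cummax)
  ends[-length(ends)]
}

#' Call differentially methylated regions
#'
#' The full DMR caller: bins both genotypes ([bin_table()]), tests each
#' bin ([fisher_bin_test()]), keeps bins with `p_value <= alpha`,
#' `|delta| >= min_delta` and the requested direction, and merges
#' significant bins whose gaps are at most `merge_gap` into DMRs.
#' Each DMR is annotated with per-context methylation levels in both
#' samples.
#'
#' @param wt,mut [methylome()] samples.
#' @param chrom_lengths Named chromosome lengths (or `NULL` to infer).
#' @param params A [dmr_params()] object.
#' @return `data.table` of class `dmr_table`: `chrom`, `start`, `end`
#'   (0-based half-open), `n_bins`, `min_p`, `median_p`, `direction`,
#'   `delta` (pooled level difference over the DMR), and per-context
#'   levels `wt_CG`, `mut_CG`, `wt_CHG`, `mut_CHG`, `wt_CHH`, `mut_CHH`.
#' @export
call_dmrs <- function(wt, mut, chrom_lengths = NULL, params = dmr_params()) {
  tested <- fisher_bin_test(bin_table(wt, mut, chrom_lengths, params),
                            params)
  p_eff <- if (params$fdr) stats::p.adjust(tested$p_value, "BH")
           else tested$p_value
  dir_ok <- switch(params$direction,
                   hyper = tested$direction == "hyper",
                   hypo = tested$direction == "hypo",
                   both = tested$direction != "none")
  sig <- tested[!is.na(p_eff) & p_eff <= params$alpha &
                  abs(tested$delta) >= params$min_delta & dir_ok]
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    n_bins = integer(), min_p = numeric(), median_p = numeric(),
    direction = character(), delta = numeric(),
    wt_CG = numeric(), mut_CG = numeric(), wt_CHG = numeric(),
    mut_CHG = numeric(), wt_CHH = numeric(), mut_CHH = numeric())
  if (!nrow(sig)) {
    data.table::setattr(empty, "class", c("dmr_table", class(empty)))
    return(empty)
  }
  data.table::setorderv(sig, c("chrom", "start"))
  merged <- merge_significant_bins(sig, params$merge_gap)
  dmrs <- merged[, .(chrom, start, end, n_bins)]
  dmrs[, `:=`(
    min_p = vapply(seq_len(.N), function(i)
      min(sig$p_value[merged$member_first[i]:merged$member_last[i]]),
      numeric(1)),
    median_p = vapply(seq_len(.N), function(i)
      stats::median(sig$p_value[merged$member_first[i]:merged$member_last[i]]),
      numeric(1))
  )]
  dmrs[, direction := params$direction]

  add_levels <- function(sample, prefix) {
    rm <- region_methylation(sample, dmrs[, .(chrom, start, end)],
                             min_cov = params$min_cov)
    for (ctx in c("CG", "CHG", "CHH")) {
      dmrs[, (paste0(prefix, "_", ctx)) :=
             rm[context == ctx][order(region_id)]$level]
    }
    rm[, .(n_meth = sum(n_meth), n_total = sum(n_total)), by = region_id][
      order(region_id)]
  }
  tot_wt <- add_levels(wt, "wt")
  tot_mut <- add_levels(mut, "mut")
  dmrs[, delta := tot_mut$n_meth / pmax(tot_mut$n_total, 1L) -
         tot_wt$n_meth / pmax(tot_wt$n_total, 1L)]
  data.table::setcolorder(dmrs, c("chrom", "start", "end", "n_bins",
                                  "min_p", "median_p", "direction", "delta"))
  data.table::setattr(dmrs, "class", c("dmr_table", class(dmrs)))
  dmrs[]
}

#' DMRs as GRanges
#'
#' @param dmrs A `dmr_table` from [call_dmrs()].
#' @return `GRanges` with the statistics as metadata columns.
#' @export
dmr_granges <- function(dmrs) {
  gr <- as_intervals(dmrs[, c("chrom", "start", "end")])
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    dmrs[, setdiff(names(dmrs), c("chrom", "start", "end")), with = FALSE])
  gr
}

#' Write DMRs as BED6+
#'
#' Columns: chrom, start, end, name, -log10(min bin p) (capped at 1000),
#' strand ".", then `n_bins` and the per-context levels of both samples.
#'
#' @param dmrs A `dmr_table`.
#' @param path Output file.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dt <- data.table::data.table(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = sprintf("DMR_%d", seq_len(nrow(dmrs))),
    score = round(pmin(-log10(dmrs$min_p), 1000), 3),
    strand = ".",
    n_bins = dmrs$n_bins,
    wt_CG = dmrs$wt_CG, mut_CG = dmrs$mut_CG,
    wt_CHG = dmrs$wt_CHG, mut_CHG = dmrs$mut_CHG,
    wt_CHH = dmrs$wt_CHH, mut_CHH = dmrs$mut_CHH)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, na = "NA")
  invisible(path)
}
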