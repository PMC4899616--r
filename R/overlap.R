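# Interval-set overlap statistics.
#
# An interval of set A is "overlapping" when its intersection with some
# single interval of B spans at least min_overlap bp (default 50). The
# chance expectation for the number of overlapping regions is A*B/N where
# N is the number of genomic bins, and enrichment is assessed with the
# hypergeometric upper tail.

#' Count overlapping intervals between two sets
#'
#' An interval of A counts (at most once) when its maximal intersection
#' with a single interval of B is at least `min_overlap` bp. With
#' `mode = "summed"` the intersections of an A interval with all of
#' (merged) B are summed before applying the threshold.
#'
#' @param setA,setB Interval sets (`GRanges` or 0-based data.frames; see
#'   [as_intervals()]). Each set is sorted and merged first.
#' @param min_overlap Minimum overlap in bp (default 50).
#' @param mode `"single"` (default, per-pair rule) or `"summed"`.
#' @return List of class `overlap_counts`: `n_A`, `n_B`, `n_overlap_A`
#'   (members of A overlapping B), `n_overlap_B` (members of B overlapping
#'   A), `min_overlap`, `mode`.
#' @export
call_overlaps <- function(setA, setB, min_overlap = 50L,
                          mode = c("single", "summed")) {
  mode <- match.arg(mode)
  a <- interval_set(setA)
  b <- interval_set(setB)
  count_dir <- function(x, y) {
    if (!length(x) || !length(y)) return(0L)
    if (mode == "single") {
      length(unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(x, y, minoverlap = min_overlap,
                                    ignore.strand = TRUE))))
    } else {
      hits <- GenomicRanges::findOverlaps(x, y, ignore.strand = TRUE)
      if (!length(hits)) return(0L)
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        x[S4Vectors::queryHits(hits)], y[S4Vectors::subjectHits(hits)]))
      # y is merged, so per-pair pieces are disjoint and sum cleanly
      tot <- tapply(w, S4Vectors::queryHits(hits), sum)
      sum(tot >= min_overlap)
    }
  }
  structure(list(n_A = length(a), n_B = length(b),
                 n_overlap_A = count_dir(a, b),
                 n_overlap_B = count_dir(b, a),
                 min_overlap = as.integer(min_overlap), mode = mode),
            class = "overlap_counts")
}

#' Expected number of overlapping regions by chance
#'
#' `A * B / N`, with A and B the two set sizes and N the number of
#' genomic bins in the analysed genome. N must be supplied explicitly
#' (e.g. total 50-bp bins, or testable bins only); it is never inferred.
#'
#' @param n_A,n_B Set sizes.
#' @param N_bins Population size (number of bins), > 0.
#' @return Expected overlap count (real).
#' @export
expected_overlap <- function(n_A, n_B, N_bins) {
  if (any(N_bins <= 0)) stop("N_bins must be > 0")
  if (any(n_A < 0) || any(n_B < 0)) stop("set sizes must be >= 0")
  n_A * n_B / N_bins
}

#' Hypergeometric enrichment of interval-set overlap
#'
#' Upper-tail probability `P[X >= n_overlap]` with
#' `X ~ Hypergeometric(N_bins, n_B, n_A)`: the chance of at least the
#' observed number of overlaps when `n_A` regions are placed among
#' `N_bins` bins of which `n_B` are covered by the other set.
#'
#' @param n_A,n_B Set sizes.
#' @param n_overlap Observed overlap count, `<= min(n_A, n_B)`.
#' @param N_bins Population size, `>= max(n_A, n_B)`.
#' @return The p-value (upper tail including the observed count).
#' @export
hypergeometric_enrichment <- function(n_A, n_B, n_overlap, N_bins) {
  if (any(n_overlap < 0) || any(n_overlap > pmin(n_A, n_B)) ||
      any(n_A > N_bins) || any(n_B > N_bins) || any(N_bins <= 0)) {
    stop("need 0 <= n_overlap <= min(n_A, n_B) <= N_bins")
  }
  stats::phyper(n_overlap - 1, n_B, N_bins - n_B, n_A, lower.tail = FALSE)
}

#' Overlap percentage
#'
#' `100 * n_overlap / n_total`, unrounded. Use [format_percent()] /
#' [ratio_report()] for the reporting convention (one decimal, two
#' decimals below 1%).
#'
#' @param n_overlap Numerator count.
#' @param n_total Denominator count, > 0.
#' @return Percentage (numeric, unrounded).
#' @export
overlap_percentage <- function(n_overlap, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0")
  100 * n_overlap / n_total
}

#' Full overlap enrichment result for two interval sets
#'
#' Combines [call_overlaps()], [expected_overlap()] and
#' [hypergeometric_enrichment()] into one record.
#'
#' @inheritParams call_overlaps
#' @param N_bins Population size for the null (required, see
#'   [expected_overlap()]).
#' @return List of class `overlap_result` with the counts, `expected`,
#'   `pct_A` (percent of A overlapping), `p_value` and `N_bins`.
#' @export
overlap_enrichment <- function(setA, setB, min_overlap = 50L, N_bins,
                               mode = c("single", "summed")) {
  cnt <- call_overlaps(setA, setB, min_overlap, mode)
  structure(c(cnt, list(
    expected = expected_overlap(cnt$n_A, cnt$n_B, N_bins),
    pct_A = if (cnt$n_A > 0) overlap_percentage(cnt$n_overlap_A, cnt$n_A)
            else NA_real_,
    p_value = hypergeometric_enrichment(cnt$n_A, cnt$n_B,
                                        min(cnt$n_overlap_A,
                                            min(cnt$n_A, cnt$n_B)),
                                        N_bins),
    N_bins = N_bins)), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d of %d regions in A overlap >= %d bp with B (%d regions); ",
    x$n_overlap_A, x$n_A, x$min_overlap, x$n_B),
    sprintf("expected %.2f by chance (N = %s bins), hypergeometric p = %.3g\n",
            x$expected, format(x$N_bins, big.mark = ","), x$p_value),
    sep = "")
  invisible(x)
}

#' Pairwise and triple overlap counts for up to three DMR sets
#'
#' Produces a Venn-style count table: for each set, its size, the number
#' of its members overlapping each other set (by the `min_overlap`
#' single-interval rule) and the number overlapping both other sets.
#'
#' @param sets Named list of 2 or 3 interval sets.
#' @param min_overlap Minimum overlap in bp (default 50).
#' @return `data.table` with one row per (set, counterpart) plus
#'   `both`-counterpart rows for three sets.
#' @export
venn_overlap_table <- function(sets, min_overlap = 50L) {
  stopifnot(length(sets) %in% c(2L, 3L), !is.null(names(sets)))
  sets <- lapply(sets, interval_set)
  rows <- list()
  for (a in names(sets)) {
    others <- setdiff(names(sets), a)
    mem <- lapply(others, function(b) {
      h <- GenomicRanges::findOverlaps(sets[[a]], sets[[b]],
                                       minoverlap = min_overlap,
                                       ignore.strand = TRUE)
      unique(S4Vectors::queryHits(h))
    })
    for (i in seq_along(others)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        set = a, n = length(sets[[a]]), counterpart = others[i],
        n_overlap = length(mem[[i]]))
    }
    if (length(others) == 2L) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        set = a, n = length(sets[[a]]),
        counterpart = paste(others, collapse = "&"),
        n_overlap = length(intersect(mem[[1L]], mem[[2L]])))
    }
  }
  data.table::rbindlist(rows)
}
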