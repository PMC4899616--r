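# Interval containers and BED I/O.
#
# In memory, interval sets are GRanges (1-based, closed). Tabular/BED
# representations are 0-based half-open. These helpers own the conversion;
# nothing else in the package converts coordinates.

#' Coerce to a GRanges interval set
#'
#' Accepts a `GRanges` (returned as-is, metadata kept) or a data.frame with
#' `chrom`, `start`, `end` columns in 0-based half-open (BED) convention.
#'
#' @param x Intervals as `GRanges` or BED-style data.frame.
#' @return A `GRanges`.
#' @export
as_intervals <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    if (nrow(x) == 0L) return(GenomicRanges::GRanges())
    if (any(x$end < x$start)) stop("interval with end < start")
    return(GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
      strand = if ("strand" %in% names(x)) x$strand else "*"
    ))
  }
  stop("cannot interpret intervals of class ", paste(class(x), collapse = "/"))
}

#' Build a sorted, merged interval set
#'
#' Sorts and merges (unions) overlapping or bookended intervals, the
#' canonical form used by the overlap statistics.
#'
#' @param x Intervals (see [as_intervals()]).
#' @param label Optional set label, stored as metadata.
#' @return A sorted, disjoint `GRanges`.
#' @export
interval_set <- function(x, label = NULL) {
  gr <- GenomicRanges::reduce(GenomicRanges::sort(as_intervals(x)))
  if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
  gr
}

#' Read a BED file as GRanges
#'
#' Supports BED3+ (chrom, start, end, then optional name, score, strand).
#' BED's 0-based half-open coordinates are converted to 1-based closed.
#'
#' @param path BED file.
#' @return A `GRanges`; column 4 (if present) becomes `name` metadata.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("BED file needs at least 3 columns: ", path)
  gr <- GenomicRanges::GRanges(
    seqnames = dt[[1L]],
    ranges = IRanges::IRanges(start = dt[[2L]] + 1L, end = dt[[3L]]),
    strand = if (ncol(dt) >= 6L) ifelse(dt[[6L]] %in% c("+", "-"), dt[[6L]], "*")
             else "*"
  )
  if (ncol(dt) >= 4L) S4Vectors::mcols(gr)$name <- as.character(dt[[4L]])
  if (ncol(dt) >= 5L) S4Vectors::mcols(gr)$score <- dt[[5L]]
  gr
}

#' Write GRanges to BED6
#'
#' @param gr A `GRanges`; `name`/`score` metadata columns are used if
#'   present.
#' @param path Output file.
#' @export
write_bed <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if ("name" %in% names(mc)) mc$name else paste0("region_", seq_along(gr)),
    score = if ("score" %in% names(mc)) mc$score else 0,
    strand = st
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# 0-based half-open data.table view of a GRanges
.gr_to_bed_dt <- function(gr) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}
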