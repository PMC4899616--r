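# Methylome samples: per-cytosine counts, coverage filter, region levels.

#' Construct a methylome sample
#'
#' A methylome sample is a coordinate-sorted table of strand-resolved
#' cytosines with methylated/total read counts, labelled by genotype.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `strand`
#'   (`+`/`-`), `context` (`CG`/`CHG`/`CHH`), `n_meth`, `n_total`
#'   (optionally `tri`).
#' @param label Genotype/sample label.
#' @return A `data.table` of class `methylome`, sorted by
#'   (`chrom`, `pos`, `strand`) with no duplicate sites.
#' @export
methylome <- function(sites, label = "sample") {
  dt <- data.table::as.data.table(sites)
  req <- c("chrom", "pos", "strand", "context", "n_meth", "n_total")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(dt$n_meth < 0) || any(dt$n_total < dt$n_meth)) {
    stop("counts must satisfy 0 <= n_meth <= n_total")
  }
  if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.table::setorderv(dt, c("chrom", "pos", "strand"))
  if (anyDuplicated(dt, by = c("chrom", "pos", "strand"))) {
    stop("duplicate site (chrom, pos, strand) in sample '", label, "'")
  }
  data.table::setattr(dt, "label", label)
  data.table::setattr(dt, "class", c("methylome", class(dt)))
  dt
}

#' @export
print.methylome <- function(x, ...) {
  cat("methylome sample '", attr(x, "label"), "': ",
      format(nrow(x), big.mark = ","), " cytosines on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  NextMethod()
}

#' Sample label of a methylome
#' @param x A `methylome`.
#' @return The genotype label.
#' @export
sample_label <- function(x) attr(x, "label")

#' Read a Bismark-style cytosine report
#'
#' Tab-separated, no header: `chrom`, `pos` (1-based), `strand`,
#' `count_methylated`, `count_unmethylated`, `context`, and optionally the
#' trinucleotide. This is the dialect written by [write_cx_report()] and by
#' Bismark's cytosine/CX reports.
#'
#' @param path Report file.
#' @param label Sample label (defaults to the file name).
#' @param genome Optional `methdmr_genome`; when supplied the context
#'   column is recomputed from the reference instead of trusted.
#' @return A [methylome()] sample. Ambiguous-context sites are dropped.
#' @export
read_cytosine_report <- function(path, label = NULL,
                                 genome = NULL) {
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  dt <- suppressWarnings(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = "character", fill = TRUE))
  if (nrow(dt) == 0L || ncol(dt) == 0L) {
    return(methylome(data.table::data.table(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), n_meth = integer(), n_total = integer()
    ), label = label))
  }
  if (ncol(dt) < 6L) stop("cytosine report needs >= 6 columns: ", path)
  meth <- suppressWarnings(as.integer(dt[[4L]]))
  unmeth <- suppressWarnings(as.integer(dt[[5L]]))
  pos <- suppressWarnings(as.integer(dt[[2L]]))
  bad <- which(is.na(pos) | pos < 1L | is.na(meth) | meth < 0L |
               is.na(unmeth) | unmeth < 0L |
               !dt[[3L]] %in% c("+", "-"))
  if (length(bad)) {
    stop("malformed cytosine report line ", bad[1L], " in ", path, ": ",
         paste(unlist(dt[bad[1L]]), collapse = "\t"))
  }
  out <- data.table::data.table(
    chrom = dt[[1L]], pos = pos, strand = dt[[3L]],
    context = dt[[6L]], n_meth = meth, n_total = meth + unmeth
  )
  if (ncol(dt) >= 7L) out[, tri := dt[[7L]]]
  if (!is.null(genome)) {
    out[, context := classify_context(genome, chrom = .BY$chrom,
                                      pos = pos, strand = strand),
        by = "chrom"]
  }
  out <- out[context %in% c("CG", "CHG", "CHH")]
  methylome(out, label = label)
}

#' Write a Bismark-style cytosine report
#'
#' Tab-separated, no header: chrom, pos, strand, methylated count,
#' unmethylated count, context, trinucleotide.
#'
#' @param sample A [methylome()] sample.
#' @param path Output file.
#' @export
write_cx_report <- function(sample, path) {
  dt <- data.table::data.table(
    chrom = sample$chrom, pos = sample$pos, strand = sample$strand,
    n_meth = sample$n_meth, n_unmeth = sample$n_total - sample$n_meth,
    context = sample$context,
    tri = if ("tri" %in% names(sample)) sample$tri else "NNN"
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Coverage filter for cytosine sites
#'
#' A site enters any methylation-level or DMR computation only when its
#' total read count reaches `min_cov` (default 3, i.e. at least threefold
#' coverage).
#'
#' @param n_total Total read counts (vector) or a [methylome()] sample.
#' @param min_cov Minimum coverage, a positive integer.
#' @return Logical vector.
#' @export
site_passes_coverage <- function(n_total, min_cov = 3) {
  if (min_cov < 1) stop("min_cov must be >= 1")
  if (inherits(n_total, "methylome") || is.data.frame(n_total)) {
    n_total <- n_total$n_total
  }
  n_total >= min_cov
}

#' Per-region, per-context methylation levels
#'
#' Pools read counts over coverage-passing cytosines within each region,
#' separately per context. The default `weighted` mode computes the
#' read-weighted level sum(meth)/sum(total); `site_mean` averages per-site
#' levels instead. The level is `NA` where no passing reads fall in the
#' region.
#'
#' @param sample A [methylome()] sample.
#' @param regions Regions as `GRanges` or 0-based half-open data.frame
#'   (`chrom`, `start`, `end`).
#' @param min_cov Coverage filter (default 3).
#' @param mode `"weighted"` (default) or `"site_mean"`.
#' @return `data.table` with one row per region x context: `region_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `context`, `level`,
#'   `n_meth`, `n_total`, `n_sites_passing`.
#' @export
region_methylation <- function(sample, regions, min_cov = 3,
                               mode = c("weighted", "site_mean")) {
  mode <- match.arg(mode)
  gr <- as_intervals(regions)
  reg <- .gr_to_bed_dt(gr)
  reg[, region_id := seq_len(.N)]

  sites <- sample[site_passes_coverage(sample, min_cov)]
  grid <- data.table::CJ(region_id = reg$region_id,
                         context = c("CG", "CHG", "CHH"))
  out <- merge(grid, reg, by = "region_id")

  if (nrow(sites)) {
    # site pos is 1-based; region [start,end) 0-based <=> pos in [start+1,end]
    s <- sites[, .(chrom, pos, context, n_meth, n_total)]
    hits <- s[reg, on = .(chrom, pos > start, pos <= end),
              .(region_id = i.region_id, context = x.context,
                n_meth = x.n_meth, n_total = x.n_total),
              nomatch = NULL, allow.cartesian = TRUE]
    agg <- hits[, .(
      n_meth = sum(n_meth), n_total = sum(n_total),
      n_sites_passing = .N,
      site_mean = mean(n_meth / n_total)
    ), by = .(region_id, context)]
    out <- merge(out, agg, by = c("region_id", "context"), all.x = TRUE)
  } else {
    out[, `:=`(n_meth = NA_integer_, n_total = NA_integer_,
               n_sites_passing = NA_integer_, site_mean = NA_real_)]
  }
  out[is.na(n_meth), `:=`(n_meth = 0L, n_total = 0L, n_sites_passing = 0L)]
  if (mode == "weighted") {
    out[, level := ifelse(n_total > 0, n_meth / n_total, NA_real_)]
  } else {
    out[, level := ifelse(n_total > 0, site_mean, NA_real_)]
  }
  out[, site_mean := NULL]
  data.table::setorderv(out, c("region_id", "context"))
  data.table::setcolorder(out, c("region_id", "chrom", "start", "end",
                                 "context", "level", "n_meth", "n_total",
                                 "n_sites_passing"))
  out[]
}
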