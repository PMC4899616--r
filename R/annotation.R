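# Feature annotation, DMR genomic composition, gene-body metaprofiles.

#' Read a gene/TE annotation
#'
#' Accepts GFF3 (feature types configurable; genes keep their strand) or
#' BED with the feature class in column 4 (values matching `gene` or the
#' TE types). BED coordinates are 0-based half-open, GFF3 1-based closed.
#'
#' @param path Annotation file (`.gff`/`.gff3` or `.bed`).
#' @param gene_types GFF3 `type` values treated as genes (default `gene`).
#' @param te_types GFF3 `type` values treated as transposable elements.
#' @return List of class `feature_annotation`: `genes` (stranded
#'   `GRanges`) and `tes` (`GRanges`).
#' @export
read_annotation <- function(path,
                            gene_types = "gene",
                            te_types = c("transposable_element",
                                         "transposable_element_gene")) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("no feature lines in GFF3 file: ", path)
    dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                            fill = TRUE)
    if (ncol(dt) < 8L) stop("not a GFF3 file: ", path)
    mk <- function(types) {
      sub <- dt[dt[[3L]] %in% types]
      GenomicRanges::GRanges(
        seqnames = sub[[1L]],
        ranges = IRanges::IRanges(start = sub[[4L]], end = sub[[5L]]),
        strand = ifelse(sub[[7L]] %in% c("+", "-"), sub[[7L]], "*"))
    }
    ann <- list(genes = mk(gene_types), tes = mk(te_types))
  } else {
    gr <- read_bed(path)
    cls <- S4Vectors::mcols(gr)$name
    if (is.null(cls)) stop("BED annotation needs a class in column 4")
    ann <- list(genes = gr[cls %in% c("gene", gene_types)],
                tes = gr[cls %in% c("TE", te_types)])
  }
  structure(ann, class = "feature_annotation")
}

#' Build an annotation from GRanges
#'
#' @param genes Stranded `GRanges` of gene spans.
#' @param tes `GRanges` of transposable elements.
#' @return A `feature_annotation`.
#' @export
feature_annotation <- function(genes, tes = GenomicRanges::GRanges()) {
  structure(list(genes = genes, tes = tes), class = "feature_annotation")
}

#' Genomic composition of a DMR set
#'
#' Assigns each DMR to exactly one of `genic`, `TE`, `intergenic` by a
#' priority rule (default genic > TE > intergenic) with a >= 1 bp overlap
#' criterion, and tabulates counts and percentages.
#'
#' @param dmrs DMRs (`dmr_table`, `GRanges`, or 0-based data.frame).
#' @param annotation A `feature_annotation`.
#' @param priority Assignment order for DMRs hitting several categories.
#' @return List of class `composition_result`: `assignment` (per-DMR
#'   category), `table` (`data.table` of category, n, pct), `n_dmrs`.
#' @export
classify_dmrs <- function(dmrs, annotation,
                          priority = c("genic", "TE", "intergenic")) {
  stopifnot(inherits(annotation, "feature_annotation"),
            setequal(priority, c("genic", "TE", "intergenic")))
  gr <- if (methods::is(dmrs, "GRanges")) dmrs
        else as_intervals(as.data.frame(dmrs))
  n <- length(gr)
  hit <- list(
    genic = GenomicRanges::countOverlaps(gr, annotation$genes,
                                         ignore.strand = TRUE) > 0,
    TE = GenomicRanges::countOverlaps(gr, annotation$tes,
                                      ignore.strand = TRUE) > 0)
  hit$intergenic <- rep(TRUE, n)
  category <- rep(NA_character_, n)
  for (cat in priority) {
    category[is.na(category) & hit[[cat]]] <- cat
  }
  counts <- table(factor(category, levels = c("genic", "TE", "intergenic")))
  tab <- data.table::data.table(
    category = names(counts), n = as.integer(counts),
    pct = if (n > 0) 100 * as.integer(counts) / n else NA_real_)
  structure(list(assignment = category, table = tab[], n_dmrs = n),
            class = "composition_result")
}

#' @export
print.composition_result <- function(x, ...) {
  cat("DMR genomic composition (n =", x$n_dmrs, "):\n")
  print(x$table)
  invisible(x)
}

#' Gene-body methylation metaprofile
#'
#' Average methylation per context across a set of genes, over
#' `flank_bins` fixed-width upstream bins covering `flank` bp, `body_bins`
#' linearly rescaled gene-body bins, and `flank_bins` downstream bins.
#' Minus-strand genes are orientation-flipped so upstream (5', TSS side)
#' is always on the left. Per-bin values are pooled read counts
#' (sum meth / sum total) over all coverage-passing sites of all genes.
#'
#' @param sample A [methylome()] sample.
#' @param genes Stranded `GRanges` of gene spans (1-based closed).
#' @param flank Flank width in bp (default 1000).
#' @param body_bins Number of scaled gene-body bins (default 20).
#' @param flank_bins Number of bins per flank (default 10).
#' @param min_cov Coverage filter (default 3).
#' @return List of class `metaprofile`: `profile` (3 x total-bins matrix
#'   of levels, rows CG/CHG/CHH, `NA` where no data), `meth`, `total`
#'   (count matrices), `bins` (bin labels), and the geometry parameters.
#' @export
gene_metaprofile <- function(sample, genes, flank = 1000L, body_bins = 20L,
                             flank_bins = 10L, min_cov = 3L) {
  stopifnot(methods::is(genes, "GRanges"))
  nb <- 2L * flank_bins + body_bins
  ctxs <- c("CG", "CHG", "CHH")
  meth <- matrix(0, 3L, nb, dimnames = list(ctxs, NULL))
  total <- matrix(0, 3L, nb, dimnames = list(ctxs, NULL))
  fw <- flank / flank_bins

  sites <- data.table::as.data.table(
    sample[site_passes_coverage(sample, min_cov)])
  data.table::setkey(sites, chrom, pos)

  for (i in seq_along(genes)) {
    cn <- as.character(GenomicRanges::seqnames(genes)[i])
    s <- GenomicRanges::start(genes)[i]
    e <- GenomicRanges::end(genes)[i]
    neg <- as.character(GenomicRanges::strand(genes)[i]) == "-"
    win <- sites[.(cn)][pos >= s - flank & pos <= e + flank]
    if (!nrow(win) || anyNA(win$pos)) next
    p <- win$pos
    # strand-aware distances from the TSS/TTS make the binning exactly
    # orientation-invariant (no post-hoc index flipping)
    d_up <- if (neg) p - e else s - p          # bp upstream of the TSS
    d_dn <- if (neg) s - p else p - e          # bp downstream of the TTS
    o_body <- if (neg) e - p else p - s        # 0-based offset into the body
    idx <- integer(length(p))
    up <- d_up >= 1L
    dn <- d_dn >= 1L
    body <- !up & !dn
    idx[up] <- flank_bins + 1L - pmin(flank_bins,
                                      as.integer(ceiling(d_up[up] / fw)))
    idx[body] <- flank_bins + pmin(
      body_bins, floor(o_body[body] / (e - s + 1) * body_bins) + 1L)
    idx[dn] <- flank_bins + body_bins +
      pmin(flank_bins, as.integer(ceiling(d_dn[dn] / fw)))
    ci <- match(win$context, ctxs)
    ok <- !is.na(ci)
    if (!any(ok)) next
    cell <- (idx[ok] - 1L) * 3L + ci[ok]
    am <- rowsum(win$n_meth[ok], cell)
    at <- rowsum(win$n_total[ok], cell)
    cells <- as.integer(rownames(am))
    meth[cells] <- meth[cells] + am[, 1L]
    total[cells] <- total[cells] + at[, 1L]
  }
  prof <- ifelse(total > 0, meth / total, NA_real_)
  labels <- c(paste0("up_", seq_len(flank_bins)),
              paste0("body_", seq_len(body_bins)),
              paste0("down_", seq_len(flank_bins)))
  colnames(prof) <- colnames(meth) <- colnames(total) <- labels
  structure(list(profile = prof, meth = meth, total = total, bins = labels,
                 flank = flank, body_bins = body_bins,
                 flank_bins = flank_bins, n_genes = length(genes)),
            class = "metaprofile")
}

#' Write a metaprofile matrix
#'
#' Tab-separated context x bin matrix of levels.
#'
#' @param mp A `metaprofile`.
#' @param path Output file.
#' @export
write_metaprofile <- function(mp, path) {
  dt <- data.table::as.data.table(mp$profile, keep.rownames = "context")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
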