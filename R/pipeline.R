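# End-to-end pipeline and reporting helpers.

#' Format a percentage for reporting
#'
#' One decimal place, two decimals below 1% (so small enrichment
#' backgrounds like 0.68% keep their precision).
#'
#' @param percent Percentage value(s).
#' @return Character vector like `"39.6%"` or `"0.68%"`.
#' @export
format_percent <- function(percent) {
  ifelse(percent < 1,
         sprintf("%.2f%%", percent),
         sprintf("%.1f%%", percent))
}

#' Report a count ratio as a percentage
#'
#' Renders `numerator / denominator` in the conventional results style:
#' `"48.8% (40/82)"`, with thousands separators inside the parenthetical
#' and two decimals for percentages below 1%.
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @return Character scalar (vectorised over inputs).
#' @export
ratio_report <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  pct <- overlap_percentage(numerator, denominator)
  sprintf("%s (%s/%s)", format_percent(pct),
          format(numerator, big.mark = ",", scientific = FALSE,
                 trim = TRUE),
          format(denominator, big.mark = ",", scientific = FALSE,
                 trim = TRUE))
}

#' Read a key: value run configuration file
#'
#' Plain-text `key: value` lines ('#' comments and blank lines ignored).
#' Values are parsed as numbers where possible; comma-separated values
#' become vectors.
#'
#' @param path Config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexpr(":", ln, fixed = TRUE), invert = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    vals <- trimws(strsplit(kv[2L], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (anyNA(num)) vals else num
  }
  out
}

.log_msg <- function(log_con, ...) {
  line <- paste0(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  message(line)
  if (!is.null(log_con)) writeLines(line, log_con)
  invisible(NULL)
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a wild-type/mutant methylome pair with planted hyper-DMRs,
#' calls DMRs, scores them against the planted truth, computes the
#' overlap/enrichment statistics, the genomic composition and the
#' gene-body metaprofile, and writes every table plus a parameter-echoing
#' summary to `out_dir`. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @param params A [dmr_params()].
#' @param out_dir Output directory (created if needed).
#' @param write_cx Also write the two cytosine reports (large; default
#'   `FALSE`).
#' @return (Invisibly) a list with the computed objects: `dmrs`, `truth`,
#'   `recovery` (fraction of planted regions hit >= 50 bp), `precision_bp`
#'   (fraction of called DMR bases inside planted regions), `enrichment`
#'   (an `overlap_result` vs the truth), `composition`, `metaprofile`,
#'   `n_bins`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         params = dmr_params(),
                         out_dir = tempfile("methdmr_run_"),
                         write_cx = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)

  .log_msg(log_con, "pipeline start; seed = ", config$seed)
  for (k in c("chrom_lengths", "gc", "te_fraction", "gene_fraction",
              "mean_depth", "fixed_depth", "n_dmrs", "dmr_width",
              "dmr_delta", "seed")) {
    .log_msg(log_con, "config ", k, ": ",
             paste(unlist(config[[k]]), collapse = ", "))
  }
  .log_msg(log_con, "dmr params: ",
           paste(names(params), vapply(params, function(x)
             paste(x, collapse = ","), character(1)),
             sep = "=", collapse = "; "))

  study <- simulate_methylome_study(config)
  .log_msg(log_con, "simulated ", nrow(study$wt), " cytosine sites, ",
           length(study$planted), " planted DMRs")
  if (write_cx) {
    write_cx_report(study$wt, file.path(out_dir, "wt.cx.txt"))
    write_cx_report(study$mut, file.path(out_dir, "mut.cx.txt"))
  }
  if (length(study$planted)) {
    write_bed(study$planted, file.path(out_dir, "planted_truth.bed"))
  }

  lens <- genome_lengths(study$genome)
  dmrs <- call_dmrs(study$wt, study$mut, lens, params)
  write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
  .log_msg(log_con, "called ", nrow(dmrs), " DMRs")

  n_bins <- sum(ceiling(lens / params$bin_size))
  truth <- study$planted
  called <- dmr_granges(dmrs)

  recovery <- NA_real_
  precision_bp <- NA_real_
  enr <- NULL
  if (length(truth)) {
    hit <- GenomicRanges::findOverlaps(truth, called, minoverlap = 50L,
                                       ignore.strand = TRUE)
    recovery <- length(unique(S4Vectors::queryHits(hit))) / length(truth)
    if (length(called)) {
      inside <- sum(GenomicRanges::width(GenomicRanges::intersect(
        GenomicRanges::reduce(called), GenomicRanges::reduce(truth),
        ignore.strand = TRUE)))
      precision_bp <- inside / sum(GenomicRanges::width(
        GenomicRanges::reduce(called)))
    }
    enr <- overlap_enrichment(called, truth, min_overlap = 50L,
                              N_bins = n_bins)
  }

  ann <- classmap_annotation(study$classmap)
  comp <- classify_dmrs(dmrs, ann)
  data.table::fwrite(comp$table, file.path(out_dir, "composition.tsv"),
                     sep = "\t")
  mp <- gene_metaprofile(study$mut, ann$genes, min_cov = params$min_cov)
  write_metaprofile(mp, file.path(out_dir, "metaprofile.tsv"))

  summary_path <- file.path(out_dir, "summary.txt")
  sm <- c(
    sprintf("planted DMRs: %d", length(truth)),
    sprintf("called DMRs: %d (N = %d bins of %d bp)",
            nrow(dmrs), n_bins, params$bin_size),
    if (length(truth)) sprintf(
      "planted regions recovered (>=50 bp overlap): %s",
      ratio_report(length(unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(truth, called, minoverlap = 50L,
                                    ignore.strand = TRUE)))),
        length(truth))),
    if (!is.na(precision_bp)) sprintf(
      "called DMR bases inside planted regions: %.1f%%",
      100 * precision_bp),
    if (!is.null(enr)) sprintf(
      "enrichment vs planted truth: observed %d, expected %.2f, p = %.3g",
      enr$n_overlap_A, enr$expected, enr$p_value),
    sprintf("composition: %s",
            paste(sprintf("%s %d", comp$table$category, comp$table$n),
                  collapse = ", ")))
  writeLines(sm, summary_path)
  .log_msg(log_con, "pipeline done; outputs in ", out_dir)

  invisible(list(dmrs = dmrs, truth = truth, recovery = recovery,
                 precision_bp = precision_bp, enrichment = enr,
                 composition = comp, metaprofile = mp, n_bins = n_bins,
                 out_dir = out_dir, study = study))
}
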