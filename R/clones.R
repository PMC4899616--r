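# Locus-specific clone-based bisulfite sequencing.
#
# Bisulfite PCR reads one strand: unmethylated C appears as T in the
# clone, methylated C stays C. Only top-strand amplicons are modeled;
# for a bottom-strand locus, reverse-complement the reference first.

#' Amplicon reference for clone-based bisulfite analysis
#'
#' Stores the (top-strand) reference sequence of a bisulfite-PCR target
#' and the positions/contexts of its cytosines.
#'
#' @param name Locus name.
#' @param sequence Reference nucleotide sequence (top strand).
#' @return List of class `amplicon_reference`: `name`, `sequence`,
#'   `positions` (1-based cytosine positions), `contexts` (per cytosine;
#'   `ambiguous` at the 3' edge where the window runs out).
#' @export
amplicon_reference <- function(name, sequence) {
  g <- as_genome(stats::setNames(toupper(sequence), "amplicon"))
  calls <- enumerate_cytosines(g)
  calls <- calls[strand == "+"]
  if (!nrow(calls)) stop("amplicon '", name, "' contains no cytosine")
  structure(list(name = name, sequence = unclass(g)[["amplicon"]],
                 positions = calls$pos, contexts = calls$context),
            class = "amplicon_reference")
}

#' Load an amplicon reference and clone sequences from FASTA
#'
#' The first record is the reference; the remaining records are clones.
#'
#' @param ref_path FASTA with the reference (first record used).
#' @param clones_path FASTA of clone sequences.
#' @return List: `reference` (an [amplicon_reference()]), `clones` (named
#'   character vector).
#' @export
read_amplicon_fasta <- function(ref_path, clones_path) {
  ref <- Biostrings::readDNAStringSet(ref_path)
  cl <- Biostrings::readDNAStringSet(clones_path)
  list(reference = amplicon_reference(names(ref)[1L],
                                      as.character(ref[[1L]])),
       clones = stats::setNames(as.character(cl), names(cl)))
}

#' Call per-site methylation from clone sequences
#'
#' Clones must align end-to-end to the reference (equal length; gapped
#' alignments must be resolved upstream). At each reference cytosine, a
#' clone base `C` is called methylated, `T` unmethylated, anything else
#' missing.
#'
#' @param reference An [amplicon_reference()].
#' @param clones Character vector (or `DNAStringSet`) of clone sequences.
#' @return Character matrix (clones x cytosine columns) of class
#'   `clone_call_matrix` with entries `methylated`/`unmethylated`/
#'   `missing`; attributes `positions`, `contexts`, `duplicates`
#'   (advisory indices of clones identical in sequence to an earlier
#'   clone; nothing is dropped).
#' @export
call_clones <- function(reference, clones) {
  stopifnot(inherits(reference, "amplicon_reference"))
  nm <- names(clones)
  clones <- toupper(as.character(clones))
  names(clones) <- nm
  L <- nchar(reference$sequence)
  if (any(nchar(clones) != L)) {
    bad <- which(nchar(clones) != L)[1L]
    stop("clone ", bad, " length ", nchar(clones)[bad],
         " does not match reference length ", L,
         " (supply a pre-aligned, equal-length sequence)")
  }
  if (is.null(names(clones))) names(clones) <- paste0("clone_", seq_along(clones))
  mat <- matrix("missing", nrow = length(clones),
                ncol = length(reference$positions),
                dimnames = list(names(clones),
                                paste0("pos_", reference$positions)))
  for (i in seq_along(clones)) {
    b <- substring(clones[i], reference$positions, reference$positions)
    mat[i, ] <- ifelse(b == "C", "methylated",
                       ifelse(b == "T", "unmethylated", "missing"))
  }
  structure(mat, class = c("clone_call_matrix", class(mat)),
            positions = reference$positions,
            contexts = reference$contexts,
            duplicates = which(duplicated(clones)))
}

#' Per-context methylation summary of a clone call matrix
#'
#' Levels are methylated / (methylated + unmethylated) per context;
#' missing calls are excluded. Denominators are reported explicitly.
#'
#' @param mat A `clone_call_matrix` from [call_clones()].
#' @return `data.table`: `context`, `n_meth`, `n_unmeth`, `n_sites`
#'   (columns of that context), `level` (`NA` when no calls).
#' @export
summarize_clones <- function(mat) {
  ctx <- attr(mat, "contexts")
  out <- data.table::rbindlist(lapply(c("CG", "CHG", "CHH"), function(cc) {
    cols <- which(ctx == cc)
    m <- sum(mat[, cols, drop = FALSE] == "methylated")
    u <- sum(mat[, cols, drop = FALSE] == "unmethylated")
    data.table::data.table(context = cc, n_meth = m, n_unmeth = u,
                           n_sites = length(cols),
                           level = if (m + u > 0) m / (m + u) else NA_real_)
  }))
  out[]
}

#' Per-site methylation frequencies of a clone call matrix
#'
#' @param mat A `clone_call_matrix`.
#' @return `data.table`: `pos`, `context`, `n_meth`, `n_unmeth`, `level`.
#' @export
clone_site_levels <- function(mat) {
  m <- colSums(mat == "methylated")
  u <- colSums(mat == "unmethylated")
  data.table::data.table(
    pos = attr(mat, "positions"), context = attr(mat, "contexts"),
    n_meth = as.integer(m), n_unmeth = as.integer(u),
    level = ifelse(m + u > 0, m / (m + u), NA_real_))
}

#' Bisulfite conversion check per clone
#'
#' Advisory QC: the fraction of CHH calls that are methylated per clone.
#' A fully unconverted clone shows 1.0; values above `threshold` are
#' flagged. No clone is dropped.
#'
#' @param mat A `clone_call_matrix`.
#' @param threshold Flagging threshold (default 0.9).
#' @return `data.table`: `clone`, `chh_meth_fraction`, `flagged`.
#' @export
conversion_check <- function(mat, threshold = 0.9) {
  cols <- which(attr(mat, "contexts") == "CHH")
  sub <- mat[, cols, drop = FALSE]
  m <- rowSums(sub == "methylated")
  u <- rowSums(sub == "unmethylated")
  frac <- ifelse(m + u > 0, m / (m + u), NA_real_)
  data.table::data.table(clone = rownames(mat),
                         chh_meth_fraction = frac,
                         flagged = !is.na(frac) & frac > threshold)
}

#' Simulate bisulfite clones from per-site methylation probabilities
#'
#' Each clone draws each cytosine independently Bernoulli(m_site):
#' methylated sites keep `C`, unmethylated become `T`. Non-cytosine bases
#' are copied from the reference.
#'
#' @param reference An [amplicon_reference()].
#' @param m_sites Per-cytosine methylation probabilities (recycled to the
#'   number of reference cytosines).
#' @param n_clones Number of clones.
#' @param seed RNG seed.
#' @return Named character vector of clone sequences.
#' @export
simulate_clones <- function(reference, m_sites, n_clones = 50L, seed = 1L) {
  stopifnot(inherits(reference, "amplicon_reference"))
  set.seed(seed)
  m_sites <- rep_len(m_sites, length(reference$positions))
  base <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
  out <- vapply(seq_len(n_clones), function(i) {
    b <- base
    meth <- stats::runif(length(m_sites)) < m_sites
    b[reference$positions] <- ifelse(meth, "C", "T")
    paste(b, collapse = "")
  }, character(1))
  stats::setNames(out, paste0("clone_", seq_len(n_clones)))
}
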