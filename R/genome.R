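#' Load a reference genome from FASTA
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file and returns the
#' genome as a named character vector of upper-case sequences over the
#' alphabet `A,C,G,T,N`. Soft-masked (lower-case) bases are promoted to
#' upper case; any other IUPAC code or stray character is mapped to `N`.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector (one element per chromosome) of class
#'   `methdmr_genome`.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read genome FASTA: ", path)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  as_genome(stats::setNames(as.character(seqs), nm))
}

#' Construct a genome object from in-memory sequences
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @return Named character vector of class `methdmr_genome`, normalized to
#'   upper-case `A,C,G,T,N`.
#' @export
as_genome <- function(sequences) {
  if (inherits(sequences, "methdmr_genome")) {
    return(sequences)
  }
  if (is.null(names(sequences)) || any(names(sequences) == "") ||
      anyNA(names(sequences))) {
    stop("every sequence must be named")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence name: ",
         names(sequences)[duplicated(names(sequences))][1L])
  }
  s <- toupper(sequences)
  s <- vapply(s, function(x) gsub("[^ACGTN]", "N", x), character(1))
  structure(s, class = "methdmr_genome")
}

#' Chromosome lengths of a genome
#'
#' @param genome A `methdmr_genome` (see [load_genome()]).
#' @return Named integer vector of sequence lengths.
#' @export
genome_lengths <- function(genome) {
  vapply(unclass(genome), nchar, integer(1))
}

#' @export
print.methdmr_genome <- function(x, ...) {
  cat("methdmr genome:", length(x), "sequence(s),",
      format(sum(genome_lengths(x)), big.mark = ","), "bp total\n")
  invisible(x)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a genome
#'
#' @param genome A `methdmr_genome`.
#' @return The reverse-complemented genome (same names).
#' @export
revcomp_genome <- function(genome) {
  s <- vapply(unclass(genome), function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }, character(1))
  as_genome(s)
}
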