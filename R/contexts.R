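# Cytosine context classification (CG / CHG / CHH, H = A, C or T).
#
# A context call is strand-resolved: a "+" call at position p refers to a C
# at p on the forward strand; a "-" call at p refers to a G at p on the
# forward strand (i.e. a C on the reverse strand). The context is read from
# the two bases immediately 3' of the C on its own strand. CG needs only
# one downstream base; CHG/CHH need two. Any N (or running off the end of
# the sequence) in the needed window makes the call "ambiguous"; ambiguous
# sites are excluded from all downstream statistics.

.CTX_LEVELS <- c("CG", "CHG", "CHH", "ambiguous")
.H_BASES <- c("A", "C", "T")

# context from the two downstream bases on the C's own strand (NA = absent)
.ctx_from_downstream <- function(n1, n2) {
  ctx <- rep("ambiguous", length(n1))
  is_cg <- !is.na(n1) & n1 == "G"
  ctx[is_cg] <- "CG"
  h1 <- !is.na(n1) & n1 %in% .H_BASES
  is_chg <- h1 & !is.na(n2) & n2 == "G"
  ctx[is_chg] <- "CHG"
  is_chh <- h1 & !is.na(n2) & n2 %in% .H_BASES
  ctx[is_chh] <- "CHH"
  ctx
}

# per-chromosome classification of every cytosine on both strands;
# returns a data.table(pos, strand, context, tri) in coordinate order with
# "+" before "-" at equal positions
.chrom_cytosines <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  out <- list()

  ip <- which(ch == "C")
  if (length(ip)) {
    n1 <- ch[ip + 1L]            # indexing past the end yields NA
    n2 <- ch[ip + 2L]
    n1[!is.na(n1) & n1 == "N"] <- NA
    n2[!is.na(n2) & n2 == "N"] <- NA
    out$plus <- data.table::data.table(
      pos = ip, strand = "+",
      context = .ctx_from_downstream(n1, n2),
      tri = paste0("C", ifelse(is.na(n1), "N", n1), ifelse(is.na(n2), "N", n2))
    )
  }

  im <- which(ch == "G")
  if (length(im)) {
    # downstream on the reverse strand = upstream on forward, complemented
    p1 <- im - 1L
    p2 <- im - 2L
    n1 <- rep(NA_character_, length(im))
    n2 <- rep(NA_character_, length(im))
    ok1 <- p1 >= 1L
    ok2 <- p2 >= 1L
    n1[ok1] <- unname(.COMPLEMENT[ch[p1[ok1]]])
    n2[ok2] <- unname(.COMPLEMENT[ch[p2[ok2]]])
    n1[!is.na(n1) & n1 == "N"] <- NA
    n2[!is.na(n2) & n2 == "N"] <- NA
    out$minus <- data.table::data.table(
      pos = im, strand = "-",
      context = .ctx_from_downstream(n1, n2),
      tri = paste0("C", ifelse(is.na(n1), "N", n1), ifelse(is.na(n2), "N", n2))
    )
  }

  if (!length(out)) {
    return(data.table::data.table(pos = integer(), strand = character(),
                                  context = character(), tri = character()))
  }
  dt <- data.table::rbindlist(out)
  data.table::setorderv(dt, c("pos", "strand"))  # "+" sorts before "-"
  dt
}

#' Classify the context of a cytosine
#'
#' Reads the two bases immediately 3' of the cytosine on its own strand and
#' returns `CG` if the next base is `G`, `CHG` if the base after next is
#' `G`, `CHH` if both downstream bases are in `{A,C,T}`, and `ambiguous`
#' if a needed base is `N` or lies beyond the sequence end. `CG` requires
#' only one downstream base; `CHG`/`CHH` require two.
#'
#' @param genome A `methdmr_genome`.
#' @param chrom Chromosome name.
#' @param pos 1-based position(s) of the cytosine. For `strand = "-"` the
#'   forward-strand base at `pos` must be `G`.
#' @param strand `"+"` or `"-"`, recycled against `pos`.
#' @return Character vector of contexts (`CG`, `CHG`, `CHH`, `ambiguous`).
#' @export
classify_context <- function(genome, chrom, pos, strand = "+") {
  genome <- as_genome(genome)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  seq <- unclass(genome)[[chrom]]
  L <- nchar(seq)
  n <- max(length(pos), length(strand))
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  if (any(pos < 1L | pos > L)) stop("position outside chromosome ", chrom)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")

  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  base <- ch[pos]
  need <- ifelse(strand == "+", "C", "G")
  if (any(base != need)) {
    i <- which(base != need)[1L]
    stop("no cytosine at ", chrom, ":", pos[i], " on strand ", strand[i],
         " (forward-strand base is ", base[i], ")")
  }

  step <- ifelse(strand == "+", 1L, -1L)
  grab <- function(p) {
    v <- rep(NA_character_, n)
    ok <- p >= 1L & p <= L
    v[ok] <- ch[p[ok]]
    flip <- ok & strand == "-"
    v[flip] <- unname(.COMPLEMENT[v[flip]])
    v[!is.na(v) & v == "N"] <- NA
    v
  }
  .ctx_from_downstream(grab(pos + step), grab(pos + 2L * step))
}

#' Enumerate every cytosine in a genome with its context
#'
#' Walks both strands of every chromosome and reports one row per cytosine
#' in coordinate order (`+` before `-` at equal positions). Ambiguous
#' contexts (an `N` or the sequence end inside the classification window)
#' are included and flagged.
#'
#' @param genome A `methdmr_genome`.
#' @param chroms Optional subset of chromosome names.
#' @return A `data.table` with columns `chrom`, `pos` (1-based), `strand`,
#'   `context` (one of `CG`, `CHG`, `CHH`, `ambiguous`) and `tri` (the
#'   cytosine plus its two downstream bases on its own strand, `N`-padded).
#' @export
enumerate_cytosines <- function(genome, chroms = NULL) {
  genome <- as_genome(genome)
  if (is.null(chroms)) chroms <- names(genome)
  parts <- lapply(chroms, function(cn) {
    dt <- .chrom_cytosines(unclass(genome)[[cn]])
    if (nrow(dt)) dt[, chrom := cn]
    dt
  })
  dt <- data.table::rbindlist(parts, use.names = TRUE, fill = TRUE)
  if (!nrow(dt)) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), context = character(),
                                  tri = character()))
  }
  data.table::setcolorder(dt, c("chrom", "pos", "strand", "context", "tri"))
  dt[]
}

#' Write a context table
#'
#' Tab-separated `chrom`, `pos`, `strand`, `context` (no header).
#'
#' @param calls Output of [enumerate_cytosines()].
#' @param path Output file.
#' @export
write_context_table <- function(calls, path) {
  data.table::fwrite(calls[, c("chrom", "pos", "strand", "context")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
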