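#' G+C fraction of a nucleotide string
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` bases are excluded from the
#' denominator. Case-insensitive.
#'
#' @param seq character string over the alphabet A, C, G, T, N.
#' @return fraction in \[0, 1\], or `NA` when no unambiguous base remains.
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) return(NA_real_)
  counts <- Biostrings::letterFrequency(
    Biostrings::BString(toupper(seq)), letters = c("A", "C", "G", "T", "N"))
  if (sum(counts) < nchar(seq)) {
    seen <- unique(strsplit(toupper(seq), "", fixed = TRUE)[[1L]])
    stop("non-nucleotide character(s): ",
         paste(setdiff(seen, c("A", "C", "G", "T", "N")), collapse = ", "))
  }
  counts <- drop(counts)
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0) return(NA_real_)
  as.numeric(sum(counts[c("G", "C")]) / acgt)
}

#' Genomic subsequence on the sense strand
#'
#' @param genome named `DNAStringSet`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`; minus returns the reverse complement.
#' @return character string (empty when `start >= end`).
#' @export
fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  if (start >= end) return("")
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Mature (spliced) sequence of a TU on the sense strand
#'
#' @param tu one row of a [tu_set()] (a list or single-row data.frame).
#' @param genome named `DNAStringSet`.
#' @return character string; for minus-strand TUs the reverse complement of
#'   the concatenated exon sequence.
#' @export
mature_seq <- function(tu, genome) {
  e <- tu$exons[[1L]]
  parts <- vapply(seq_len(nrow(e)), function(i)
    fetch_seq(genome, tu$chrom, e[i, 1L], e[i, 2L]), character(1))
  s <- paste(parts, collapse = "")
  if (tu$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Concatenated intron sequence of a TU on the sense strand
#'
#' @param tu one row of a [tu_set()].
#' @param genome named `DNAStringSet`.
#' @return character string; empty for intron-less TUs.
#' @export
intron_seq <- function(tu, genome) {
  e <- tu$exons[[1L]]
  if (nrow(e) < 2L && e[1L, 1L] == tu$start && e[1L, 2L] == tu$end) return("")
  bounds <- rbind(c(tu$start, e[1L, 1L]),
                  if (nrow(e) > 1L) cbind(e[-nrow(e), 2L], e[-1L, 1L]),
                  c(e[nrow(e), 2L], tu$end))
  bounds <- bounds[bounds[, 1L] < bounds[, 2L], , drop = FALSE]
  parts <- vapply(seq_len(nrow(bounds)), function(i)
    fetch_seq(genome, tu$chrom, bounds[i, 1L], bounds[i, 2L]), character(1))
  s <- paste(parts, collapse = "")
  if (nzchar(s) && tu$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Sequence downstream of the TSS on the sense strand
#'
#' Extracts up to `span` bases of genomic sequence starting at the TSS,
#' reverse-complemented for minus-strand TUs, truncated at the chromosome
#' end.
#'
#' @param tus a [tu_set()].
#' @param genome named `DNAStringSet`.
#' @param span bp downstream of the TSS (default 1000).
#' @return named character vector (names are `tu_id`s).
#' @export
tss_seq <- function(tus, genome, span = 1000L) {
  out <- character(nrow(tus))
  for (i in seq_len(nrow(tus))) {
    L <- length(genome[[tus$chrom[i]]])
    if (tus$strand[i] == "+") {
      s0 <- tus$start[i]; e0 <- min(tus$start[i] + span, L)
    } else {
      s0 <- max(tus$end[i] - span, 0L); e0 <- tus$end[i]
    }
    out[i] <- fetch_seq(genome, tus$chrom[i], s0, e0, tus$strand[i])
  }
  names(out) <- tus$tu_id
  out
}

#' Extract the TU features used in the SEM
#'
#' Nine features per TU: G+C content and length of the 5'UTR, CDS, 3'UTR and
#' intron(s), plus the splice-junction density. The intron length is the
#' span length minus the total exon length; the splice-junction density is
#' the number of introns divided by the mature RNA length. UTR/CDS regions
#' are taken from CDS coordinates expressed on the mature (spliced) RNA;
#' non-coding TUs get `NA` for the CDS-dependent fields while intron and
#' splice-junction features are still computed. All sequence features are on
#' the sense strand.
#'
#' @param tus a [tu_set()].
#' @param genome named `DNAStringSet` covering the TU spans.
#' @param cds optional `data.frame(tu_id, cds_start, cds_end)` with 0-based
#'   half-open CDS coordinates on the mature RNA.
#' @return `data.frame` with columns `tu_id`, `gc_5utr`, `gc_cds`, `gc_3utr`,
#'   `gc_intron`, `len_5utr`, `len_cds`, `len_3utr`, `len_intron`,
#'   `splice_junction_density`, `mature_length`.
#' @export
extract_features <- function(tus, genome, cds = NULL) {
  n <- nrow(tus)
  out <- data.frame(tu_id = tus$tu_id,
                    gc_5utr = NA_real_, gc_cds = NA_real_,
                    gc_3utr = NA_real_, gc_intron = NA_real_,
                    len_5utr = NA_integer_, len_cds = NA_integer_,
                    len_3utr = NA_integer_,
                    len_intron = (tus$end - tus$start) - tus$mature_length,
                    splice_junction_density =
                      (vapply(tus$exons, nrow, integer(1)) - 1L) /
                      tus$mature_length,
                    mature_length = tus$mature_length,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tu <- tus[i, , drop = FALSE]
    mseq <- mature_seq(tu, genome)
    iseq <- intron_seq(tu, genome)
    if (nzchar(iseq)) out$gc_intron[i] <- gc_content(iseq)
    if (!is.null(cds)) {
      j <- match(tu$tu_id, cds$tu_id)
      if (!is.na(j)) {
        cs <- cds$cds_start[j]; ce <- cds$cds_end[j]
        ml <- nchar(mseq)
        if (cs < 0 || ce > ml || cs >= ce)
          stop("CDS outside mature coordinates for ", tu$tu_id)
        out$len_5utr[i] <- cs
        out$len_cds[i] <- ce - cs
        out$len_3utr[i] <- ml - ce
        if (cs > 0) out$gc_5utr[i] <- gc_content(substr(mseq, 1L, cs))
        out$gc_cds[i] <- gc_content(substr(mseq, cs + 1L, ce))
        if (ce < ml) out$gc_3utr[i] <- gc_content(substr(mseq, ce + 1L, ml))
      }
    }
  }
  out
}

#' Assemble a SEM feature matrix from a feature table
#'
#' Length features are log10(1 + bp)-transformed (the SEM is linear in log
#' space); G+C fractions and the splice-junction density enter untransformed.
#' An intercept column is prepended. Rows with any missing selected feature
#' are dropped (with their ids recorded in the `dropped` attribute).
#'
#' @param fv output of [extract_features()].
#' @param columns feature columns to use.
#' @return numeric matrix with rownames `tu_id` and attribute `dropped`.
#' @export
feature_matrix <- function(fv, columns = c("gc_3utr", "gc_5utr", "gc_cds",
                                           "gc_intron", "len_3utr",
                                           "len_5utr", "len_cds",
                                           "len_intron",
                                           "splice_junction_density")) {
  stopifnot(all(columns %in% colnames(fv)))
  M <- as.matrix(fv[, columns, drop = FALSE])
  lencols <- grep("^len_", columns)
  if (length(lencols)) M[, lencols] <- log10(1 + M[, lencols])
  keep <- stats::complete.cases(M)
  X <- cbind(`(intercept)` = 1, M[keep, , drop = FALSE])
  rownames(X) <- fv$tu_id[keep]
  attr(X, "dropped") <- fv$tu_id[!keep]
  X
}
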