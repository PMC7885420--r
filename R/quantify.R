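reads_to_granges <- function(reads) {
  GenomicRanges::GRanges(reads$chrom,
                         IRanges::IRanges(reads$pos + 1L, width = 1L),
                         strand = reads$strand)
}

#' Count PRO-seq 3'-end positions in the TU body window
#'
#' Counts single-base polymerase positions strictly inside
#' `[start + omit_tss, end - omit_tes)`, excluding the promoter-proximal
#' pause region downstream of the TSS and the deceleration zone upstream of
#' the TES. Counting is strand-matched. TUs whose span cannot accommodate the
#' two excluded windows get `NA` (excluded, not an error); exclusions are
#' reported in the `excluded` attribute.
#'
#' @param tus a [tu_set()].
#' @param reads `data.frame` of point reads (`chrom`, `pos`, `strand`), as
#'   from [read_reads()] with `assay = "PRO"`.
#' @param omit_tss,omit_tes bp excluded downstream of the TSS / upstream of
#'   the TES (defaults 500 bp each). The excluded windows follow biological
#'   orientation, so for a minus-strand TU `omit_tss` trims the right edge.
#' @return Integer vector aligned to `tus`, `NA` for excluded TUs.
#' @export
count_pro <- function(tus, reads, omit_tss = 500L, omit_tes = 500L) {
  minus <- tus$strand == "-"
  lo <- ifelse(minus, tus$start + omit_tes, tus$start + omit_tss)
  hi <- ifelse(minus, tus$end - omit_tss, tus$end - omit_tes)
  ok <- hi - lo > 0L
  counts <- rep(NA_integer_, nrow(tus))
  if (any(ok) && nrow(reads) > 0L) {
    win <- GenomicRanges::GRanges(tus$chrom[ok],
                                  IRanges::IRanges(lo[ok] + 1L, hi[ok]),
                                  strand = tus$strand[ok])
    counts[ok] <- GenomicRanges::countOverlaps(win, reads_to_granges(reads),
                                               ignore.strand = FALSE)
  } else if (any(ok)) {
    counts[ok] <- 0L
  }
  attr(counts, "excluded") <- tus$tu_id[!ok]
  counts
}

#' Count RNA-seq read points in exons or introns
#'
#' Exonic mode counts read points inside any exon of the TU; intronic mode
#' counts points inside the TU span but in no exon. Intron-less TUs get `NA`
#' in intronic mode (not applicable).
#'
#' @param tus a [tu_set()].
#' @param reads `data.frame` of point reads, as from [read_reads()].
#' @param mode `"exonic"` (default steady-state abundance) or `"intronic"`
#'   (nascent-proxy variant).
#' @param stranded count only reads whose strand matches the TU (default);
#'   set `FALSE` for unstranded RNA-seq libraries.
#' @return Integer vector aligned to `tus`.
#' @export
count_rna <- function(tus, reads, mode = c("exonic", "intronic"),
                      stranded = TRUE) {
  mode <- match.arg(mode)
  n <- nrow(tus)
  rg <- reads_to_granges(reads)
  ex_tu <- rep(seq_len(n), vapply(tus$exons, nrow, integer(1)))
  exm <- do.call(rbind, tus$exons)
  ex <- GenomicRanges::GRanges(tus$chrom[ex_tu],
                               IRanges::IRanges(exm[, 1L] + 1L, exm[, 2L]),
                               strand = tus$strand[ex_tu])
  exonic <- as.integer(rowsum(
    GenomicRanges::countOverlaps(ex, rg, ignore.strand = !stranded),
    ex_tu, reorder = TRUE))
  # rowsum drops absent groups only if a TU had zero exons, which tu_set forbids
  if (mode == "exonic") return(exonic)
  span <- GenomicRanges::GRanges(tus$chrom,
                                 IRanges::IRanges(tus$start + 1L, tus$end),
                                 strand = tus$strand)
  total <- GenomicRanges::countOverlaps(span, rg, ignore.strand = !stranded)
  intronic <- as.integer(total - exonic)
  intronic[tus$mature_length >= tus$end - tus$start] <- NA_integer_
  intronic
}

#' Transcripts-per-million normalization
#'
#' `tpm_i = 1e6 * (c_i / L_i) / sum_k (c_k / L_k)`. `NA` counts (excluded
#' TUs) are omitted from the denominator and stay `NA`. An all-zero count
#' vector maps to all zeros.
#'
#' @param counts non-negative integer vector.
#' @param eff_len positive effective lengths (bp), same length.
#' @return Numeric TPM vector summing to 1e6 over non-`NA` entries whenever
#'   any count is positive.
#' @export
tpm <- function(counts, eff_len) {
  stopifnot(length(counts) == length(eff_len))
  if (any(!is.na(eff_len) & eff_len <= 0))
    stop("non-positive effective length at index ",
         which(!is.na(eff_len) & eff_len <= 0)[1L])
  rate <- counts / eff_len
  denom <- sum(rate, na.rm = TRUE)
  if (denom == 0) return(ifelse(is.na(rate), NA_real_, 0))
  1e6 * rate / denom
}

#' Pool replicate counts and report concordance
#'
#' Pooled counts are replicate sums. As a concordance diagnostic the Spearman
#' correlation between replicate TPM vectors is reported (the mean over all
#' replicate pairs when more than two).
#'
#' @param count_mat matrix, TUs x replicates.
#' @param eff_len effective lengths used for the TPM concordance diagnostic.
#' @return list with `pooled` (integer vector) and `concordance` (numeric,
#'   `NA` when only one replicate).
#' @export
pool_replicates <- function(count_mat, eff_len) {
  count_mat <- as.matrix(count_mat)
  pooled <- rowSums(count_mat)
  J <- ncol(count_mat)
  conc <- NA_real_
  if (J >= 2L) {
    tpms <- matrix(apply(count_mat, 2L, tpm, eff_len = eff_len),
                   nrow = nrow(count_mat))
    pairs <- utils::combn(J, 2L)
    rhos <- apply(pairs, 2L, function(p)
      stats::cor(tpms[, p[1L]], tpms[, p[2L]], method = "spearman",
                 use = "complete.obs"))
    conc <- mean(rhos)
  }
  list(pooled = pooled, concordance = conc)
}

#' Quantify PRO-seq and RNA-seq expression per TU
#'
#' Runs the full counting and normalization step: PRO-seq 3' ends counted in
#' the body window (TSS/TES exclusion), RNA-seq points counted in exons (or
#' introns), per-replicate TPM, and pooled TPM. PRO-seq TPM uses the full TU
#' length by default (`pro_len = "full"`), with the trimmed body-window
#' length available as an alternative; RNA-seq uses the mature length in
#' exonic mode and the total intron length in intronic mode.
#'
#' @param tus a [tu_set()].
#' @param pro_reads,rna_reads a read `data.frame` or a list of them (one per
#'   replicate).
#' @param omit_tss,omit_tes PRO-seq exclusion windows in bp.
#' @param mode RNA counting mode, `"exonic"` or `"intronic"`.
#' @param pro_len `"full"` (span length) or `"body"` (window length) as the
#'   PRO-seq TPM effective length.
#' @param rna_stranded strand-matched RNA counting (default `TRUE`).
#' @return `data.frame` (class `"expression_set"`) with per-replicate counts
#'   and TPMs, pooled TPMs `pro_tpm` / `rna_tpm`, effective lengths, and the
#'   replicate-concordance attributes `pro_concordance`, `rna_concordance`.
#' @export
quantify <- function(tus, pro_reads, rna_reads,
                     omit_tss = 500L, omit_tes = 500L,
                     mode = c("exonic", "intronic"),
                     pro_len = c("full", "body"), rna_stranded = TRUE) {
  mode <- match.arg(mode)
  pro_len <- match.arg(pro_len)
  if (is.data.frame(pro_reads)) pro_reads <- list(pro_reads)
  if (is.data.frame(rna_reads)) rna_reads <- list(rna_reads)

  pc <- vapply(pro_reads, function(r)
    as.integer(count_pro(tus, r, omit_tss, omit_tes)), integer(nrow(tus)))
  rc <- vapply(rna_reads, function(r)
    as.integer(count_rna(tus, r, mode, stranded = rna_stranded)),
    integer(nrow(tus)))
  pc <- matrix(pc, nrow = nrow(tus)); rc <- matrix(rc, nrow = nrow(tus))

  span_len <- tus$end - tus$start
  body_len <- pmax(span_len - omit_tss - omit_tes, 0L)
  pro_eff <- if (pro_len == "full") span_len else body_len
  rna_eff <- if (mode == "exonic") tus$mature_length
             else span_len - tus$mature_length
  rna_eff[rna_eff == 0L] <- NA_integer_

  pro_pool <- pool_replicates(pc, pro_eff)
  rna_pool <- pool_replicates(rc, rna_eff)
  out <- data.frame(tu_id = tus$tu_id, stringsAsFactors = FALSE)
  colnames(pc) <- paste0("pro_count_", seq_len(ncol(pc)))
  colnames(rc) <- paste0("rna_count_", seq_len(ncol(rc)))
  ptpm <- matrix(apply(pc, 2L, tpm, eff_len = pro_eff), nrow = nrow(tus))
  rtpm <- matrix(apply(rc, 2L, tpm, eff_len = rna_eff), nrow = nrow(tus))
  colnames(ptpm) <- paste0("pro_tpm_", seq_len(ncol(pc)))
  colnames(rtpm) <- paste0("rna_tpm_", seq_len(ncol(rc)))
  out <- cbind(out, pc, rc, ptpm, rtpm)
  out$pro_tpm <- tpm(pro_pool$pooled, pro_eff)
  out$rna_tpm <- tpm(rna_pool$pooled, rna_eff)
  out$pro_eff_len <- pro_eff
  out$rna_eff_len <- rna_eff
  attr(out, "pro_concordance") <- pro_pool$concordance
  attr(out, "rna_concordance") <- rna_pool$concordance
  attr(out, "excluded") <- tus$tu_id[is.na(out$pro_tpm)]
  class(out) <- c("expression_set", "data.frame")
  out
}
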