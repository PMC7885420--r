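# Shared fixture builders. All randomness is seeded by the caller.

# two-exon plus-strand TU and a minus-strand companion on a toy chromosome
toy_tus <- function() {
  tu_set(tu_id = c("tuP", "tuM"),
         gene_id = c("gP", "gM"),
         chrom = "chr1",
         start = c(1000L, 6000L), end = c(4000L, 9000L),
         strand = c("+", "-"),
         exons = list(cbind(c(1000L, 2300L), c(2000L, 4000L)),
                      cbind(c(6000L, 7500L), c(7000L, 9000L))),
         tu_class = c("mRNA", "lincRNA"))
}

point_reads <- function(chrom, pos, strand, assay = "PRO") {
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             strand = as.character(strand),
             assay = rep_len(assay, length(pos)), stringsAsFactors = FALSE)
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

plant_motif <- function(s, motif, at) {
  paste0(substr(s, 1L, at), motif, substr(s, at + nchar(motif) + 1L,
                                          nchar(s)))
}

# brute-force membership count: points in [lo, hi) on chrom/strand
brute_count <- function(reads, chrom, lo, hi, strand = NULL) {
  sel <- reads$chrom == chrom & reads$pos >= lo & reads$pos < hi
  if (!is.null(strand)) sel <- sel & reads$strand == strand
  sum(sel)
}

# exhaustive sum over all nonzero-probability state paths of a stability HMM
enumerate_ssi <- function(seq, model) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  L <- length(ch)
  ns <- length(model$init)
  emis_of <- function(b) if (b == "N") rep(1, ns) else model$emis[, b]
  succ <- lapply(seq_len(ns), function(s) which(model$trans[s, ] > 0))
  macro_mass <- c(N = 0, U = 0, P = 0)
  e1 <- emis_of(ch[1L])
  walk <- function(state, pos, prob) {
    if (pos == L) {
      macro_mass[model$state_macro[state]] <<-
        macro_mass[model$state_macro[state]] + prob
      return(invisible(NULL))
    }
    e <- emis_of(ch[pos + 1L])
    for (s2 in succ[[state]]) {
      p2 <- prob * model$trans[state, s2] * e[s2]
      if (p2 > 0) walk(s2, pos + 1L, p2)
    }
  }
  for (s in which(model$init > 0)) {
    p0 <- model$init[s] * e1[s]
    if (p0 > 0) walk(s, 1L, p0)
  }
  1 - macro_mass["P"] / sum(macro_mass)
}

toy_hmm <- function(p_motif = 0.05) {
  stability_hmm(u1_pwm = pwm_from_consensus("GT", smooth = 0.1),
                pas_pwm = pwm_from_consensus("AA", smooth = 0.1),
                p_motif = p_motif)
}
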