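#' Canonical motif consensus sequences
#'
#' The U1 5'-splice-site consensus (`CAGGTAAGT`) and the polyadenylation
#' signal consensus (`AATAAA`) used for motif planting and as the default
#' HMM emission models.
#' @name motif_consensus
#' @export
U1_CONSENSUS <- "CAGGTAAGT"

#' @rdname motif_consensus
#' @export
PAS_CONSENSUS <- "AATAAA"

#' Default configuration for the synthetic TU generator
#'
#' The defaults describe a compact but realistic cohort: multi-exon TUs with
#' log-normal exon and intron lengths (spans of a few kb), mixed strands on
#' one synthetic chromosome, uniform base composition at G+C 0.5, and no
#' planted motifs. All fields can be overridden via the `config` argument of
#' [simulate_tus()].
#'
#' @return list of generator settings.
#' @export
synth_config <- function() {
  list(
    chrom = "chrS",
    gap_mean = 2000,            # bp between consecutive TUs
    n_exons_lambda = 2,         # exons per TU = 1 + Poisson(lambda)
    exon_meanlog = log(300), exon_sdlog = 0.6,
    intron_meanlog = log(1500), intron_sdlog = 0.8,
    min_exon = 50, min_intron = 80,
    min_span = 2200,            # keep the PRO-seq body window non-degenerate
    gc = 0.5,
    gc_gradient = NULL,         # c(from, to) over the first kb past the TSS
    class_probs = c(mRNA = 0.7, lincRNA = 0.2, eRNA = 0.1),
    strand_probs = c(`+` = 0.5, `-` = 0.5),
    # planted motifs per class: TSS-relative offsets on the sense strand
    plant = list(),             # e.g. list(mRNA = list(u1 = 50, pas = 600))
    cds_frac = c(0.2, 0.7)      # CDS on the mature RNA, mRNA class only
  )
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

plant_at <- function(seq, motif, offset) {
  # offset is 0-based from the 5' end; silently skipped if it does not fit
  if (offset + nchar(motif) > nchar(seq)) return(seq)
  paste0(substr(seq, 1L, offset), motif,
         substr(seq, offset + nchar(motif) + 1L, nchar(seq)))
}

#' Simulate transcription units and their genome
#'
#' Generates `n` TUs laid head-to-tail (with random gaps) on one synthetic
#' chromosome, each with an exon/intron structure drawn from the configured
#' length distributions, a class label, a strand, and a sense-strand sequence
#' with the configured base composition, optional 5' G+C gradient, and
#' optional planted U1 / PAS motifs at class-specific TSS-relative offsets.
#' mRNA-class TUs get a CDS on the mature RNA at the configured fractional
#' position. The generator is a pure function of `(n, seed, config)`.
#'
#' @param n number of TUs (>= 1).
#' @param seed integer RNG seed.
#' @param config overrides merged over [synth_config()].
#' @param with_sequence generate sequences and the genome (default `TRUE`);
#'   `FALSE` returns `genome = NULL` and skips motif planting, for tests that
#'   only need TU structures.
#' @return list with `tus` (a [tu_set()]), `genome` (`DNAStringSet`, or
#'   `NULL`), `cds` (`data.frame(tu_id, cds_start, cds_end)` in mature
#'   coordinates), and the evaluated `config`.
#' @export
simulate_tus <- function(n, seed = 1L, config = list(), with_sequence = TRUE) {
  if (n < 1L) stop("n must be >= 1")
  cfg <- utils::modifyList(synth_config(), config)
  set.seed(seed)
  tu_id <- sprintf("TU%04d", seq_len(n))
  cls <- sample(names(cfg$class_probs), n, replace = TRUE,
                prob = cfg$class_probs)
  strand <- sample(names(cfg$strand_probs), n, replace = TRUE,
                   prob = cfg$strand_probs)
  # all structural randomness is drawn before any sequence randomness, so TU
  # structures are identical with and without sequence generation
  spans <- vector("list", n)
  cds <- list()
  for (i in seq_len(n)) {
    ne <- if (cls[i] == "eRNA") 1L else 1L + stats::rpois(1L,
                                                          cfg$n_exons_lambda)
    elen <- pmax(round(stats::rlnorm(ne, cfg$exon_meanlog, cfg$exon_sdlog)),
                 cfg$min_exon)
    ilen <- if (ne > 1L)
      pmax(round(stats::rlnorm(ne - 1L, cfg$intron_meanlog,
                               cfg$intron_sdlog)), cfg$min_intron)
      else integer(0)
    span <- sum(elen) + sum(ilen)
    if (span < cfg$min_span) {         # pad the last exon
      elen[ne] <- elen[ne] + (cfg$min_span - span)
      span <- cfg$min_span
    }
    # exon offsets within the sense-strand span
    starts <- cumsum(c(0L, elen[-ne] + ilen))
    spans[[i]] <- cbind(start = starts, end = starts + elen)
    if (cls[i] == "mRNA") {
      ml <- sum(elen)
      cs <- floor(cfg$cds_frac[1] * ml); ce <- ceiling(cfg$cds_frac[2] * ml)
      cds[[length(cds) + 1L]] <- data.frame(tu_id = tu_id[i],
                                            cds_start = cs, cds_end = ce,
                                            stringsAsFactors = FALSE)
    }
  }
  gaps <- pmax(round(stats::rexp(n + 1L, 1 / cfg$gap_mean)), 100L)
  seqs <- character(n)
  if (with_sequence) for (i in seq_len(n)) {
    span <- max(spans[[i]][, 2L])
    s <- random_dna(span, cfg$gc)
    if (!is.null(cfg$gc_gradient)) {
      k <- min(1000L, span)
      gcs <- seq(cfg$gc_gradient[1], cfg$gc_gradient[2], length.out = k)
      head_s <- paste(vapply(gcs, function(g) random_dna(1L, g),
                             character(1)), collapse = "")
      s <- paste0(head_s, substr(s, k + 1L, span))
    }
    pl <- cfg$plant[[cls[i]]]
    if (!is.null(pl)) {
      if (!is.null(pl$u1) && !is.na(pl$u1)) s <- plant_at(s, U1_CONSENSUS,
                                                          pl$u1)
      if (!is.null(pl$pas) && !is.na(pl$pas)) s <- plant_at(s, PAS_CONSENSUS,
                                                            pl$pas)
    }
    seqs[i] <- s
  }
  widths <- vapply(spans, function(m) max(m[, 2L]), numeric(1))
  tu_start <- cumsum(gaps[seq_len(n)] + c(0, widths[-n]))
  chrom_len <- tu_start[n] + widths[n] + gaps[n + 1L]
  genome <- NULL
  if (with_sequence) {
    # genome: gaps of background sequence, TU segments in genomic orientation
    pieces <- character(2L * n + 1L)
    pos <- 0L
    for (i in seq_len(n)) {
      pieces[2L * i - 1L] <- random_dna(tu_start[i] - pos, cfg$gc)
      seg <- seqs[i]
      if (strand[i] == "-")
        seg <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seg)))
      pieces[2L * i] <- seg
      pos <- tu_start[i] + widths[i]
    }
    pieces[2L * n + 1L] <- random_dna(chrom_len - pos, cfg$gc)
    genome <- Biostrings::DNAStringSet(setNames(paste(pieces, collapse = ""),
                                                cfg$chrom))
  }
  exons <- lapply(seq_len(n), function(i) {
    e <- spans[[i]]
    if (strand[i] == "+") {
      cbind(start = tu_start[i] + e[, 1L], end = tu_start[i] + e[, 2L])
    } else {
      w <- widths[i]
      m <- cbind(start = tu_start[i] + w - e[, 2L],
                 end = tu_start[i] + w - e[, 1L])
      m[order(m[, 1L]), , drop = FALSE]
    }
  })
  tus <- tu_set(tu_id, tu_id, cfg$chrom, tu_start, tu_start + widths,
                strand, exons, cls)
  list(tus = tus,
       genome = genome,
       cds = if (length(cds)) do.call(rbind, cds) else NULL,
       config = cfg)
}

#' Map mature-RNA offsets to genomic positions
#'
#' Inverts the exon concatenation of [mature_seq()]: offset 0 is the first
#' transcribed base, so minus-strand offsets run right-to-left on the genome.
#'
#' @param tu one row of a [tu_set()].
#' @param offsets 0-based offsets on the mature RNA, all `< mature_length`.
#' @return integer vector of 0-based genomic positions.
#' @export
mature_to_genomic <- function(tu, offsets) {
  e <- tu$exons[[1L]]
  elen <- e[, 2L] - e[, 1L]
  cum <- cumsum(c(0L, elen))
  ml <- cum[length(cum)]
  stopifnot(all(offsets >= 0L & offsets < ml))
  g_off <- if (tu$strand == "-") ml - 1L - offsets else offsets
  k <- findInterval(g_off, cum, rightmost.closed = FALSE)
  e[k, 1L] + (g_off - cum[k])
}

#' Simulate replicate expression data with known ground truth
#'
#' Latent transcription rate and half-life are drawn from the generative SEM
#' (`b = X lambda + eps_b`, `t = X mu + eps_t`, `m = b + t`). Two output
#' modes cover the two layers of the pipeline:
#' \describe{
#'   \item{`"sem"`}{exact log-TPM tables with Gaussian replicate noise
#'     (`p_j = b + eps_p`, `r_j = m + eps_r`), for testing the SEM machinery
#'     on its own model.}
#'   \item{`"counts"`}{per-replicate point-read sets at a fixed sequencing
#'     depth: PRO-seq 3' ends uniform over each TU span with per-TU weight
#'     `exp(b) * span` (divided by the elongation rate when supplied),
#'     RNA-seq points uniform over the mature RNA with weight
#'     `exp(m) * mature_length`, TU totals multinomial over the depth.}
#' }
#'
#' @param tus a [tu_set()].
#' @param X feature matrix (intercept first column), rows aligned to `tus`.
#' @param lambda,mu generative coefficient vectors.
#' @param sigmas named or positional vector `(sigma_b, sigma_t, sigma_p,
#'   sigma_r)`.
#' @param J_p,J_r replicate counts (default 2 each).
#' @param depth reads per replicate per assay in counts mode (default 1e6).
#' @param mode `"sem"` or `"counts"`.
#' @param elongation optional positive per-TU elongation rates (counts mode).
#' @param seed integer RNG seed.
#' @return list with `truth` (`data.frame(tu_id, b, t, m, beta, alpha,
#'   half_life, elongation_rate)` plus the generative parameters as
#'   attributes) and either `p`/`r` log-TPM matrices (sem mode) or
#'   `pro_reads`/`rna_reads` lists of read `data.frame`s (counts mode).
#' @export
simulate_expression <- function(tus, X, lambda, mu,
                                sigmas = c(0.5, 0.4, 0.2, 0.2),
                                J_p = 2L, J_r = 2L, depth = 1e6,
                                mode = c("sem", "counts"),
                                elongation = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (depth < 0) stop("negative depth")
  X <- as.matrix(X)
  stopifnot(nrow(X) == nrow(tus))
  set.seed(seed)
  n <- nrow(tus)
  b <- as.vector(X %*% lambda) + stats::rnorm(n, 0, sigmas[1])
  t <- as.vector(X %*% mu) + stats::rnorm(n, 0, sigmas[2])
  m <- b + t
  truth <- data.frame(tu_id = tus$tu_id, b = b, t = t, m = m,
                      beta = exp(b), half_life = exp(t),
                      alpha = log(2) / exp(t),
                      elongation_rate = if (is.null(elongation)) NA_real_
                                        else elongation,
                      stringsAsFactors = FALSE)
  attr(truth, "lambda") <- lambda
  attr(truth, "mu") <- mu
  attr(truth, "sigmas") <- sigmas
  attr(truth, "seed") <- seed
  out <- list(truth = truth)
  if (mode == "sem") {
    out$p <- b + matrix(stats::rnorm(n * J_p, 0, sigmas[3]), n, J_p)
    out$r <- m + matrix(stats::rnorm(n * J_r, 0, sigmas[4]), n, J_r)
    return(out)
  }
  span <- tus$end - tus$start
  pro_w0 <- exp(b) * span
  if (!is.null(elongation)) {
    stopifnot(all(elongation > 0))
    pro_w0 <- pro_w0 / elongation
  }
  rna_w0 <- exp(m) * tus$mature_length
  draw_reads <- function(w0, sigma_rep, assay) {
    w <- w0 * exp(stats::rnorm(n, 0, sigma_rep))
    counts <- as.vector(stats::rmultinom(1L, size = depth, prob = w / sum(w)))
    idx <- rep(seq_len(n), counts)
    if (assay == "PRO") {
      pos <- tus$start[idx] +
        floor(stats::runif(length(idx)) * span[idx])
    } else {
      pos <- integer(length(idx))
      by_tu <- split(seq_along(idx), idx)
      for (nm in names(by_tu)) {
        i <- as.integer(nm)
        sel <- by_tu[[nm]]
        offs <- floor(stats::runif(length(sel)) * tus$mature_length[i])
        pos[sel] <- mature_to_genomic(tus[i, , drop = FALSE],
                                      as.integer(offs))
      }
    }
    data.frame(chrom = tus$chrom[idx], pos = as.integer(pos),
               strand = tus$strand[idx], assay = assay,
               stringsAsFactors = FALSE)
  }
  out$pro_reads <- lapply(seq_len(J_p), function(j)
    draw_reads(pro_w0, sigmas[3], "PRO"))
  out$rna_reads <- lapply(seq_len(J_r), function(j)
    draw_reads(rna_w0, sigmas[4], "RNA"))
  out
}

#' Simulate an epigenomic signal track with class-dependent peaks
#'
#' Deposits a Gaussian-shaped peak at a fixed oriented offset from each
#' locus's TSS, with per-locus amplitude, plus optional white noise, on a
#' zero baseline. Useful as a ground-truth fixture for [meta_signal()] and
#' [stratified_profiles()].
#'
#' @param loci `data.frame` with `chrom`, `tss`, `strand` (as for
#'   [meta_signal()]).
#' @param amplitudes numeric vector, one peak height per locus.
#' @param seqlens named integer vector of chromosome lengths.
#' @param peak_at oriented offset of the peak center from the TSS (default
#'   +1000 bp).
#' @param peak_sd Gaussian peak width (default 200 bp).
#' @param noise_sd white-noise standard deviation (default 0).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return a `signal_track`.
#' @export
simulate_track <- function(loci, amplitudes, seqlens, peak_at = 1000L,
                           peak_sd = 200, noise_sd = 0, seed = 1L) {
  stopifnot(nrow(loci) == length(amplitudes))
  set.seed(seed)
  track <- lapply(seqlens, function(L)
    if (noise_sd > 0) stats::rnorm(L, 0, noise_sd) else numeric(L))
  half <- 4L * ceiling(peak_sd)
  offs <- seq.int(-half, half)
  shape <- exp(-offs^2 / (2 * peak_sd^2))
  for (i in seq_len(nrow(loci))) {
    ch <- loci$chrom[i]
    if (!ch %in% names(track)) next
    first <- if (loci$strand[i] == "+") loci$tss[i] else loci$tss[i] - 1L
    center <- if (loci$strand[i] == "+") first + peak_at else first - peak_at
    gpos <- center + offs
    keep <- gpos >= 0L & gpos < length(track[[ch]])
    track[[ch]][gpos[keep] + 1L] <- track[[ch]][gpos[keep] + 1L] +
      amplitudes[i] * shape[keep]
  }
  structure(track, class = "signal_track")
}
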