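#' @import methods
#' @importFrom stats setNames
NULL

#' Construct a set of transcription units
#'
#' A transcription-unit (TU) table is the central annotation object: one row
#' per TU with its genomic span, strand, exon structure and class label.
#' Coordinates are 0-based half-open throughout the package; GTF input is
#' converted on ingest.
#'
#' @param tu_id character vector of unique TU identifiers.
#' @param gene_id character vector of gene identifiers (may repeat across
#'   isoforms).
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open span, `start < end`.
#' @param strand character vector, `"+"` or `"-"`.
#' @param exons list of two-column integer matrices (`start`, `end`), one per
#'   TU, 0-based half-open, non-overlapping and within the span. Exons are
#'   sorted on ingest.
#' @param tu_class character vector of class labels, one of `"mRNA"`,
#'   `"lincRNA"`, `"antisense"`, `"pseudogene"`, `"eRNA"`, `"other"`.
#' @return A `data.frame` of class `"tu_set"` with a list column `exons` and
#'   a derived `mature_length` column (sum of exon lengths).
#' @export
tu_set <- function(tu_id, gene_id, chrom, start, end, strand, exons,
                   tu_class = "other") {
  n <- length(tu_id)
  chrom <- rep_len(chrom, n)
  strand <- rep_len(strand, n)
  stopifnot(length(gene_id) == n, length(start) == n,
            length(end) == n, length(exons) == n)
  tu_class <- rep_len(tu_class, n)
  known <- c("mRNA", "lincRNA", "antisense", "pseudogene", "eRNA", "other")
  if (!all(tu_class %in% known))
    stop("unknown tu_class value(s): ",
         paste(setdiff(unique(tu_class), known), collapse = ", "))
  if (anyDuplicated(tu_id))
    stop("duplicated tu_id values")
  exons <- lapply(exons, function(e) {
    e <- matrix(as.integer(e), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    e[order(e[, 1L]), , drop = FALSE]
  })
  tus <- data.frame(tu_id = as.character(tu_id),
                    gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand),
                    tu_class = tu_class,
                    stringsAsFactors = FALSE)
  tus$exons <- exons
  tus$mature_length <- vapply(exons, function(e)
    sum(e[, 2L] - e[, 1L]), integer(1))
  validate_tus(tus)
  tus <- tus[order(tus$chrom, tus$start, tus$tu_id), , drop = FALSE]
  rownames(tus) <- NULL
  class(tus) <- c("tu_set", "data.frame")
  tus
}

validate_tus <- function(tus) {
  bad <- which(tus$start >= tus$end)
  if (length(bad))
    stop("TU with start >= end: ", paste(tus$tu_id[bad], collapse = ", "))
  if (!all(tus$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  for (i in seq_len(nrow(tus))) {
    e <- tus$exons[[i]]
    if (nrow(e) < 1L)
      stop("TU ", tus$tu_id[i], " has no exons")
    if (any(e[, 1L] >= e[, 2L]))
      stop("TU ", tus$tu_id[i], " has an empty/inverted exon")
    if (e[1L, 1L] < tus$start[i] || e[nrow(e), 2L] > tus$end[i])
      stop("TU ", tus$tu_id[i], " has an exon outside its span")
    if (nrow(e) > 1L && any(e[-1L, 1L] < e[-nrow(e), 2L]))
      stop("TU ", tus$tu_id[i], " has overlapping exons")
  }
  invisible(tus)
}

#' Parse TU annotations from GTF or BED12
#'
#' GTF coordinates (1-based, closed) are converted to the internal 0-based
#' half-open convention; BED12 is already 0-based half-open. One TU is
#' produced per transcript (GTF) or per BED record. GENCODE-style
#' `gene_type`/`transcript_type` attributes are mapped onto the internal
#' class labels when present.
#'
#' @param path path to a GTF or BED12 file, or a character vector of lines.
#' @param format `"auto"` (by extension/content), `"gtf"`, or `"bed12"`.
#' @return A [tu_set()] ordered by (chrom, start, tu_id).
#' @export
parse_annotations <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (length(path) > 1L || grepl("\t", path[1], fixed = TRUE)) {
    lines <- path
    path <- tempfile(fileext = ".txt")
    writeLines(lines, path)
    on.exit(unlink(path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.bed[0-9]*$", path, ignore.case = TRUE))
      "bed12" else "gtf"
  }
  if (format == "gtf") parse_gtf(path) else parse_bed12(path)
}

.map_class <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  out[grepl("protein_coding|^mrna$", x)] <- "mRNA"
  out[grepl("lincrna", x)] <- "lincRNA"
  out[grepl("antisense", x)] <- "antisense"
  out[grepl("pseudogene", x)] <- "pseudogene"
  out[grepl("erna|enhancer", x)] <- "eRNA"
  out
}

check_gtf_lines <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nf < 8L))
    stop("malformed GTF line ", which(body)[which(nf < 8L)[1L]],
         ": fewer than 8 tab-separated fields")
  invisible(TRUE)
}

parse_gtf <- function(path) {
  check_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  ex <- gr[meta$type == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon features")
  exm <- S4Vectors::mcols(ex)
  txid <- as.character(exm$transcript_id)
  if (anyNA(txid)) stop("GTF exon without transcript_id")
  sp <- split(seq_along(ex), txid)
  # transcript span: explicit transcript feature when present, else exon range
  tx <- gr[meta$type == "transcript"]
  tx_span <- if (length(tx)) {
    setNames(seq_along(tx), as.character(S4Vectors::mcols(tx)$transcript_id))
  } else NULL
  cls_col <- intersect(c("transcript_type", "gene_type", "transcript_biotype",
                         "gene_biotype"), colnames(exm))[1]
  ids <- names(sp)
  n <- length(ids)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  strand <- character(n); gene <- character(n); cls <- character(n)
  exons <- vector("list", n)
  st_all <- GenomicRanges::start(ex) - 1L  # to 0-based half-open
  en_all <- GenomicRanges::end(ex)
  for (k in seq_len(n)) {
    i <- sp[[k]]
    chrom[k] <- as.character(GenomicRanges::seqnames(ex))[i[1L]]
    strand[k] <- as.character(GenomicRanges::strand(ex))[i[1L]]
    gene[k] <- as.character(exm$gene_id[i[1L]])
    cls[k] <- if (!is.na(cls_col)) .map_class(as.character(exm[[cls_col]][i[1L]]))
              else "other"
    exons[[k]] <- cbind(start = st_all[i], end = en_all[i])
    if (!is.null(tx_span) && ids[k] %in% names(tx_span)) {
      j <- tx_span[[ids[k]]]
      start[k] <- GenomicRanges::start(tx)[j] - 1L
      end[k] <- GenomicRanges::end(tx)[j]
      if (min(st_all[i]) < start[k] || max(en_all[i]) > end[k])
        stop("exon outside transcript span for ", ids[k])
    } else {
      start[k] <- min(st_all[i]); end[k] <- max(en_all[i])
    }
  }
  tu_set(ids, gene, chrom, start, end, strand, exons, cls)
}

parse_bed12 <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nf < 12L))
    stop("malformed BED12 line ", body[which(nf < 12L)[1L]],
         ": fewer than 12 tab-separated fields")
  gr <- rtracklayer::import(path, format = "bed")
  n <- length(gr)
  if (n == 0L) stop("empty BED12 file")
  start <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  blocks <- S4Vectors::mcols(gr)$blocks  # 1-based ranges relative to start
  exons <- lapply(seq_len(n), function(i) {
    b <- blocks[[i]]
    cbind(start = start[i] + IRanges::start(b) - 1L,
          end = start[i] + IRanges::end(b))
  })
  ids <- as.character(S4Vectors::mcols(gr)$name)
  tu_set(ids, ids, as.character(GenomicRanges::seqnames(gr)),
         start, end, as.character(GenomicRanges::strand(gr)), exons)
}

#' Write transcription units as BED12
#'
#' Inverse of [parse_annotations()] for BED12 input; a round trip preserves
#' all coordinates and exon structures.
#'
#' @param tus a [tu_set()].
#' @param path output path.
#' @export
write_bed12 <- function(tus, path) {
  rows <- vapply(seq_len(nrow(tus)), function(i) {
    e <- tus$exons[[i]]
    paste(tus$chrom[i], tus$start[i], tus$end[i], tus$tu_id[i], 0L,
          tus$strand[i], tus$start[i], tus$start[i], "0,0,0", nrow(e),
          paste0(paste(e[, 2L] - e[, 1L], collapse = ","), ","),
          paste0(paste(e[, 1L] - tus$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Select the most abundant isoform per gene
#'
#' Keeps one TU per gene: the isoform with the highest abundance (e.g. a
#' Salmon TPM estimate supplied as an input table). Ties are broken
#' lexicographically by `tu_id`; isoforms with no abundance entry are ignored,
#' and genes with no abundance for any isoform are dropped with a warning.
#'
#' @param tus a [tu_set()] possibly holding several isoforms per `gene_id`.
#' @param abundance named numeric vector, names are `tu_id`s.
#' @return A [tu_set()] with one row per retained gene.
#' @export
select_isoform <- function(tus, abundance) {
  ab <- abundance[match(tus$tu_id, names(abundance))]
  keep_rows <- !is.na(ab)
  dropped_genes <- setdiff(unique(tus$gene_id), unique(tus$gene_id[keep_rows]))
  if (length(dropped_genes))
    warning("dropping ", length(dropped_genes),
            " gene(s) with no isoform abundance: ",
            paste(utils::head(dropped_genes, 5L), collapse = ", "))
  tus2 <- tus[keep_rows, , drop = FALSE]
  ab <- ab[keep_rows]
  ord <- order(tus2$gene_id, -ab, tus2$tu_id)
  tus2 <- tus2[ord, , drop = FALSE]
  out <- tus2[!duplicated(tus2$gene_id), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$tu_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tu_set", "data.frame")
  out
}

#' Strand-aware TSS and TES positions
#'
#' Returns the transcription start and end positions in biological
#' orientation: the TSS of a minus-strand TU is its right span boundary.
#'
#' @param tus a [tu_set()].
#' @return `data.frame` with columns `tu_id`, `tss`, `tes`.
#' @export
tss_tes <- function(tus) {
  minus <- tus$strand == "-"
  data.frame(tu_id = tus$tu_id,
             tss = ifelse(minus, tus$end, tus$start),
             tes = ifelse(minus, tus$start, tus$end),
             stringsAsFactors = FALSE)
}

#' Read mapped-read positions from BED6
#'
#' Reads are reduced to single-base point positions on ingest: PRO-seq reads
#' to the 3'-end base of the aligned interval (the position of the engaged
#' polymerase), RNA-seq reads to the interval midpoint. Positions are
#' 0-based.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @param assay `"PRO"` or `"RNA"`; controls the point reduction.
#' @return `data.frame` with columns `chrom`, `pos`, `strand`, `assay`.
#' @export
read_reads <- function(path, assay = c("PRO", "RNA")) {
  assay <- match.arg(assay)
  gr <- rtracklayer::import(path, format = "bed")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)  # half-open end
  str <- as.character(GenomicRanges::strand(gr))
  pos <- if (assay == "PRO") {
    ifelse(str == "+", end0 - 1L, start0)
  } else {
    as.integer(floor((start0 + end0 - 1L) / 2))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = as.integer(pos), strand = str, assay = assay,
             stringsAsFactors = FALSE)
}

#' Read a two-column elongation-rate table
#'
#' @param path TSV with header columns `gene_id` and `rate` (kb/min).
#' @return `data.frame` with positive `rate` values.
#' @export
read_rates <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("gene_id", "rate") %in% colnames(x)))
  if (any(!is.finite(x$rate)) || any(x$rate <= 0))
    stop("elongation rates must be positive and finite")
  x[, c("gene_id", "rate")]
}

#' Read a bedGraph signal track into dense per-chromosome vectors
#'
#' Basewise, 0-based half-open semantics. Positions not covered by any
#' bedGraph interval are 0.
#'
#' @param path bedGraph file.
#' @param seqlens named integer vector of chromosome lengths.
#' @return A named list of numeric vectors (one per chromosome), class
#'   `"signal_track"`; element `i` of a vector is the signal on base `i - 1`.
#' @export
read_bedgraph <- function(path, seqlens) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- lapply(seqlens, function(L) numeric(L))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  s <- GenomicRanges::start(gr) - 1L
  e <- GenomicRanges::end(gr)
  v <- S4Vectors::mcols(gr)$score
  if (any(!is.finite(v))) stop("non-finite value in bedGraph")
  for (i in seq_along(gr)) {
    if (!chroms[i] %in% names(track)) next
    track[[chroms[i]]][(s[i] + 1L):e[i]] <- v[i]
  }
  structure(track, class = "signal_track")
}

#' Write a tab-separated table with provenance header
#'
#' All tabular outputs share one convention: UTF-8, tab-separated, header
#' row, `.` for missing values, and a leading `#` comment carrying the
#' package version and (optionally) the run seed.
#'
#' @param x data.frame.
#' @param path output path.
#' @param seed optional integer recorded in the provenance line.
#' @export
write_tsv <- function(x, path, seed = NULL) {
  x2 <- as.data.frame(x)
  x2$exons <- NULL
  for (j in seq_along(x2)) {
    col <- x2[[j]]
    if (is.numeric(col)) col <- format(col, trim = TRUE, digits = 15)
    col[is.na(x2[[j]])] <- "."
    x2[[j]] <- col
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("decaypro"))
  writeLines(paste0("# decaypro ", ver,
                    if (!is.null(seed)) paste0(" seed=", seed)), con)
  utils::write.table(x2, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_tsv()]
#' @param path input path.
#' @return data.frame with `.` restored to `NA`.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = ".",
                    stringsAsFactors = FALSE)
}
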