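#' TSS-anchored meta-profile of a signal track
#'
#' Averages a basewise signal across strand-oriented anchor loci as a
#' function of distance from the TSS. Minus-strand loci are read
#' right-to-left so that positive offsets always point into the gene body.
#' Uncertainty is the standard error of the mean with a normal-approximation
#' 95% confidence interval (mean +/- 1.96 se).
#'
#' @param loci `data.frame` with `chrom`, `tss` (0-based; for minus-strand
#'   loci the convention of [tss_tes()], i.e. one past the first transcribed
#'   base) and `strand`.
#' @param track a `signal_track` (named list of per-chromosome numeric
#'   vectors), e.g. from [read_bedgraph()] or [simulate_track()].
#' @param upstream,downstream flank sizes in bp.
#' @param bin bin width in bp (default 1); offsets are averaged within bins.
#' @param na_skip if `TRUE`, `NA` signal values are dropped from the
#'   averages; if `FALSE` (default) they are treated as 0, the usual reading
#'   of bedGraph gaps.
#' @return list of class `"meta_profile"`: `positions` (bin start offsets,
#'   negative = upstream), `mean`, `se`, `ci_lo`, `ci_hi`, `n_loci`.
#' @export
meta_signal <- function(loci, track, upstream = 2000L, downstream = 5000L,
                        bin = 1L, na_skip = FALSE) {
  if (nrow(loci) == 0L) stop("no loci")
  W <- upstream + downstream
  offs <- seq.int(-upstream, downstream - 1L)
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(loci))) {
    ch <- loci$chrom[i]
    if (!ch %in% names(track)) { dropped <- dropped + 1L; next }
    v <- track[[ch]]
    first <- if (loci$strand[i] == "+") loci$tss[i] else loci$tss[i] - 1L
    gpos <- if (loci$strand[i] == "+") first + offs else first - offs
    if (min(gpos) < 0L || max(gpos) >= length(v)) {
      dropped <- dropped + 1L; next
    }
    x <- v[gpos + 1L]
    if (!na_skip) x[is.na(x)] <- 0
    rows[[length(rows) + 1L]] <- x
  }
  if (dropped > 0L)
    message(dropped, " locus/loci dropped (outside chromosome bounds)")
  if (!length(rows)) stop("no usable loci")
  M <- do.call(rbind, rows)
  if (bin > 1L) {
    nb <- W %/% bin
    M <- M[, seq_len(nb * bin), drop = FALSE]
    grp <- rep(seq_len(nb), each = bin)
    M <- t(apply(M, 1L, function(x) tapply(x, grp, mean, na.rm = na_skip)))
    if (nrow(M) != length(rows)) M <- t(M)  # single-bin edge case
    positions <- -upstream + (seq_len(nb) - 1L) * bin
  } else {
    positions <- offs
  }
  n <- colSums(!is.na(M))
  mu <- colMeans(M, na.rm = TRUE)
  se <- apply(M, 2L, stats::sd, na.rm = TRUE) / sqrt(n)
  structure(list(positions = positions, mean = mu, se = se,
                 ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se,
                 n_loci = nrow(M)),
            class = "meta_profile")
}

#' Meta-profiles stratified by stability class with expression matching
#'
#' Computes one meta-profile per stability class. When per-locus expression
#' values are supplied, every non-reference class is subsampled by greedy
#' nearest-neighbour matching ([match_by_expression()]) to the reference
#' class (the first element), so the classes are compared at matched PRO-seq
#' signal.
#'
#' @param loci_by_class named list of loci `data.frame`s (see
#'   [meta_signal()]); each needs at least 2 rows.
#' @param track a `signal_track`.
#' @param expr_by_class optional named list of positive expression vectors
#'   aligned row-wise to `loci_by_class`.
#' @param ... passed to [meta_signal()].
#' @return named list of `meta_profile` objects.
#' @export
stratified_profiles <- function(loci_by_class, track, expr_by_class = NULL,
                                ...) {
  stopifnot(length(loci_by_class) >= 1L)
  classes <- names(loci_by_class) %||% as.character(seq_along(loci_by_class))
  names(loci_by_class) <- classes
  if (!is.null(expr_by_class)) {
    ref_class <- classes[1L]
    ref <- expr_by_class[[ref_class]]
    names(ref) <- as.character(seq_along(ref))
    others <- lapply(expr_by_class[classes[-1L]], function(x)
      setNames(x, as.character(seq_along(x))))
    mr <- match_by_expression(ref, others)
    for (cl in classes[-1L]) {
      keep <- as.integer(mr[[cl]]$matched_id)
      loci_by_class[[cl]] <- loci_by_class[[cl]][keep, , drop = FALSE]
    }
  }
  lapply(loci_by_class, function(lc) {
    if (nrow(lc) < 2L) stop("a class has fewer than 2 matched loci")
    meta_signal(lc, track, ...)
  })
}
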