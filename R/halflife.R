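#' Unit-less relative half-life estimator
#'
#' Under a steady-state kinetic model (production rate beta, per-molecule
#' decay rate alpha, molecule count M) the decay rate is alpha = beta / M and
#' the half-life T1/2 = ln(2) M / beta. With PRO-seq TPM P proportional to
#' beta and RNA-seq TPM R proportional to M, the ratio `R / P` is a unit-less
#' estimator proportional to the true half-life. Values are comparable across
#' experiments only up to a proportionality constant.
#'
#' TUs with a zero or missing value on either axis are excluded (`NA`), never
#' mapped to 0 or Inf. An optional pseudocount added to both axes is
#' available for sensitivity analyses and defaults to off.
#'
#' @param R,P numeric vectors of RNA-seq and PRO-seq TPMs.
#' @param pseudocount non-negative value added to both R and P (default 0).
#' @return Numeric vector `R / P`, `NA` where either input is not positive.
#' @export
estimate_half_life <- function(R, P, pseudocount = 0) {
  stopifnot(length(R) == length(P), pseudocount >= 0)
  R <- R + pseudocount
  P <- P + pseudocount
  out <- ifelse(!is.na(R) & !is.na(P) & R > 0 & P > 0, R / P, NA_real_)
  out
}

#' Build a half-life table from an expression set
#'
#' Applies the expression filters, optionally corrects PRO-seq for
#' elongation rate, and computes `t_half_pr = R / P` with its log2. The
#' elongation-corrected analysis is a separate run mode: it never silently
#' replaces the uncorrected estimates.
#'
#' @param expr an `expression_set` from [quantify()] (needs `pro_tpm`,
#'   `rna_tpm`), or any data.frame with those columns plus `tu_id`.
#' @param rates optional `data.frame(gene_id, rate)` of elongation rates
#'   (kb/min); when given, transcription is measured as PRO-seq density times
#'   rate and TUs without a rate are dropped from the corrected analysis.
#' @param gene_ids character vector mapping rows of `expr` to gene ids (only
#'   needed with `rates`; defaults to `tu_id`).
#' @param pro_min,rna_min strict lower TPM bounds (defaults 10 and 1).
#' @param basis label recorded in the output (`"pro"` or `"intronic"`).
#' @return `data.frame` with `tu_id`, `t_half_pr`, `log2_t_half`, `basis`,
#'   `elongation_corrected`, `passed_filters`.
#' @export
half_life_table <- function(expr, rates = NULL, gene_ids = expr$tu_id,
                            pro_min = 10, rna_min = 1,
                            basis = c("pro", "intronic")) {
  basis <- match.arg(basis)
  P <- expr$pro_tpm
  R <- expr$rna_tpm
  corrected <- !is.null(rates)
  if (corrected) {
    r <- rates$rate[match(gene_ids, rates$gene_id)]
    if (anyNA(r))
      message(sum(is.na(r)), " TU(s) without an elongation rate omitted ",
              "from the corrected analysis")
    P <- correct_elongation(P, r)
  }
  pass <- passes_expression_filter(expr$pro_tpm, R, pro_min, rna_min)
  th <- estimate_half_life(R, P)
  th[!pass] <- NA_real_
  data.frame(tu_id = expr$tu_id,
             t_half_pr = th,
             log2_t_half = log2(th),
             basis = basis,
             elongation_corrected = corrected,
             passed_filters = pass,
             stringsAsFactors = FALSE)
}

#' Expression-filter predicate
#'
#' `TRUE` where PRO-seq TPM is strictly above `pro_min` and RNA-seq TPM
#' strictly above `rna_min`; boundary values and `NA`s fail.
#'
#' @param P,R PRO-seq and RNA-seq TPM vectors.
#' @param pro_min,rna_min strict thresholds (defaults 10 and 1 TPM).
#' @return logical vector.
#' @export
passes_expression_filter <- function(P, R, pro_min = 10, rna_min = 1) {
  !is.na(P) & !is.na(R) & P > pro_min & R > rna_min
}

#' Filter TUs on expression thresholds
#'
#' Keeps TUs with PRO-seq TPM strictly above `pro_min` and RNA-seq TPM
#' strictly above `rna_min`; boundary values are excluded.
#'
#' @param expr data.frame with `pro_tpm` and `rna_tpm` columns.
#' @param pro_min,rna_min strict thresholds (defaults 10 and 1 TPM).
#' @return The filtered subset.
#' @export
filter_expressed <- function(expr, pro_min = 10, rna_min = 1) {
  expr[passes_expression_filter(expr$pro_tpm, expr$rna_tpm,
                                pro_min, rna_min), , drop = FALSE]
}

#' Elongation-rate correction of PRO-seq abundance
#'
#' PRO-seq density reflects transcription initiation divided by polymerase
#' speed; multiplying the gene-body density by a measured elongation rate
#' recovers a quantity proportional to the transcription rate itself.
#'
#' @param P_density PRO-seq abundance (TPM) vector.
#' @param rate elongation rates (kb/min), `NA` where unavailable.
#' @return `P_density * rate`, `NA` where the rate is missing.
#' @export
correct_elongation <- function(P_density, rate) {
  stopifnot(length(P_density) == length(rate))
  if (any(!is.na(rate) & rate <= 0)) stop("elongation rates must be positive")
  P_density * rate
}

#' Partition TUs into equally sized stability classes
#'
#' Rank-based quantile partition of the half-life estimates into `k` classes
#' whose sizes differ by at most one; class 1 is the least stable. Ties are
#' broken by a stable sort on `tu_id`, so the assignment is deterministic.
#'
#' @param t_half numeric half-life estimates (finite).
#' @param tu_id identifiers used for deterministic tie-breaking.
#' @param k number of classes (default 5).
#' @return Integer vector of class labels in `1..k`.
#' @export
stability_classes <- function(t_half, tu_id = as.character(seq_along(t_half)),
                              k = 5L) {
  if (k < 2L) stop("k must be >= 2")
  ok <- is.finite(t_half)
  if (sum(ok) < k) stop("need at least k finite estimates")
  n <- sum(ok)
  ord <- order(t_half[ok], tu_id[ok])
  bounds <- diff(round(seq(0, n, length.out = k + 1L)))
  cls_sorted <- rep(seq_len(k), times = bounds)
  cls <- rep(NA_integer_, length(t_half))
  cls[which(ok)[ord]] <- cls_sorted
  cls
}

#' Split TUs into most-stable and most-unstable extremes
#'
#' Returns the indices of the top and bottom `fraction` of TUs by half-life.
#' Both sets have size `ceiling(fraction * n)` unless that would make them
#' overlap, in which case `floor(fraction * n)` is used; the sets are always
#' disjoint.
#'
#' @param t_half numeric half-life estimates.
#' @param tu_id identifiers for tie-breaking.
#' @param fraction in (0, 0.5] (default 0.2).
#' @return list with integer index vectors `stable` and `unstable`.
#' @export
split_extremes <- function(t_half, tu_id = as.character(seq_along(t_half)),
                           fraction = 0.2) {
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  ok <- which(is.finite(t_half))
  n <- length(ok)
  m <- ceiling(fraction * n)
  if (2L * m > n) m <- floor(fraction * n)
  ord <- ok[order(t_half[ok], tu_id[ok])]
  list(unstable = sort(ord[seq_len(m)]),
       stable = sort(ord[seq.int(n - m + 1L, n)]))
}

#' Classify eRNA stability from the CAGE/PRO-seq ratio
#'
#' eRNAs are too unstable for RNA-seq; CAGE substitutes as the steady-state
#' measure. TUs in the top `q` fraction by CAGE/PRO-seq ratio are called
#' stable, the bottom `q` fraction unstable, the rest intermediate. TUs with
#' no CAGE signal (or no PRO-seq signal) are excluded (`NA`).
#'
#' @param cage,pro numeric vectors of CAGE and PRO-seq signal.
#' @param q extreme fraction per tail (default 0.10).
#' @param tu_id identifiers for tie-breaking.
#' @return character vector in `{"stable", "unstable", "intermediate", NA}`.
#' @export
erna_stability_call <- function(cage, pro, q = 0.10,
                                tu_id = as.character(seq_along(cage))) {
  stopifnot(length(cage) == length(pro), q > 0, q < 0.5)
  ratio <- ifelse(!is.na(cage) & !is.na(pro) & cage > 0 & pro > 0,
                  cage / pro, NA_real_)
  out <- rep(NA_character_, length(ratio))
  ok <- which(is.finite(ratio))
  n <- length(ok)
  if (n == 0L) return(out)
  m <- max(1L, floor(q * n))
  ord <- ok[order(ratio[ok], tu_id[ok])]
  out[ok] <- "intermediate"
  out[ord[seq_len(m)]] <- "unstable"
  out[ord[seq.int(n - m + 1L, n)]] <- "stable"
  out
}
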