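#' Match TU groups to a reference by expression
#'
#' Greedy nearest-neighbour matching without replacement on log2 expression
#' (PRO-seq TPM), mirroring the default behaviour of nearest matching in
#' covariate-matching tools. Reference TUs are processed in descending order
#' of expression; each is paired with the unused candidate minimising
#' `|log2 ref - log2 candidate|`. Candidates are pre-sorted by (value, id),
#' so the result does not depend on input order; distance ties go to the
#' lower-expression candidate.
#'
#' @param reference named numeric vector of positive expression values.
#' @param others named list of named numeric vectors, one per group to be
#'   matched; every group must be at least as large as the reference.
#' @return list of class `"match_result"`: per group a `data.frame` with
#'   `ref_id`, `matched_id`, `distance` (absolute log2 difference), aligned
#'   to the (descending-expression) reference order.
#' @export
match_by_expression <- function(reference, others) {
  stopifnot(all(reference > 0), length(reference) >= 1)
  if (is.null(names(reference)))
    names(reference) <- paste0("ref", seq_along(reference))
  ref_log <- log2(reference)
  ref_ord <- order(-ref_log, names(reference))
  out <- lapply(seq_along(others), function(gi) {
    cand <- others[[gi]]
    gname <- names(others)[gi] %||% as.character(gi)
    if (length(cand) < length(reference))
      stop("group '", gname, "' has fewer candidates than the reference")
    stopifnot(all(cand > 0))
    if (is.null(names(cand))) names(cand) <- paste0("cand", seq_along(cand))
    co <- order(cand, names(cand))
    cand_log <- log2(cand)[co]
    cand_id <- names(cand)[co]
    used <- logical(length(cand))
    res <- data.frame(ref_id = names(reference)[ref_ord],
                      matched_id = NA_character_, distance = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(ref_ord)) {
      d <- abs(cand_log - ref_log[ref_ord[i]])
      d[used] <- Inf
      j <- which.min(d)
      used[j] <- TRUE
      res$matched_id[i] <- cand_id[j]
      res$distance[i] <- d[j]
    }
    res
  })
  names(out) <- names(others)
  structure(out, class = "match_result")
}

#' Compare two half-life distributions (KS test with bootstrap eCDF bands)
#'
#' Two-sample Kolmogorov-Smirnov D and asymptotic p-value, plus empirical
#' CDFs of both groups evaluated on the pooled value grid with pointwise
#' percentile bootstrap confidence bands.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param n_boot bootstrap replicates for the bands (default 1000; 0 skips
#'   the bands).
#' @param conf band coverage (default 0.95).
#' @param seed optional integer seed for the bootstrap.
#' @return list of class `"group_comparison"`: `ks_D`, `p_value`, `grid`,
#'   `ecdf_a`, `ecdf_b`, and with `n_boot > 0` the band matrices `band_a`,
#'   `band_b` (columns `lower`, `upper`).
#' @export
compare_groups <- function(a, b, n_boot = 1000L, conf = 0.95, seed = NULL) {
  if (length(a) < 2L || length(b) < 2L) stop("both groups need >= 2 values")
  kt <- suppressWarnings(stats::ks.test(a, b))
  grid <- sort(unique(c(a, b)))
  ec <- function(x) stats::ecdf(x)(grid)
  out <- list(ks_D = unname(kt$statistic), p_value = kt$p.value,
              grid = grid, ecdf_a = ec(a), ecdf_b = ec(b),
              n_a = length(a), n_b = length(b))
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    alpha <- (1 - conf) / 2
    boot_band <- function(x) {
      em <- vapply(seq_len(n_boot), function(i)
        ec(sample(x, length(x), replace = TRUE)), numeric(length(grid)))
      t(apply(em, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE))
    }
    ba <- boot_band(a); bb <- boot_band(b)
    colnames(ba) <- colnames(bb) <- c("lower", "upper")
    out$band_a <- ba
    out$band_b <- bb
  }
  structure(out, class = "group_comparison")
}
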