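test_that("PRO-seq body-window counting respects boundaries and strand", {
  tus <- tu_set("t", "t", "chr1", 1000L, 4000L, "+",
                list(cbind(1000L, 4000L)))
  ends <- point_reads("chr1", c(1499L, 1500L, 3499L, 3500L), "+")
  expect_equal(count_pro(tus, ends)[1], 2L)   # 1500 and 3499 inside window
  tus_m <- tu_set("t", "t", "chr1", 1000L, 4000L, "-",
                  list(cbind(1000L, 4000L)))
  ends_m <- point_reads("chr1", c(1499L, 1500L, 3499L, 3500L), "-")
  expect_equal(count_pro(tus_m, ends_m)[1], 2L)
  expect_equal(count_pro(tus_m, ends)[1], 0L)  # wrong strand
  # degenerate window: excluded, not an error
  short <- tu_set("s", "s", "chr1", 0L, 900L, "+", list(cbind(0L, 900L)))
  cs <- count_pro(short, ends)
  expect_true(is.na(cs[1]))
  expect_equal(attr(cs, "excluded"), "s")
})

test_that("RNA counting separates exonic and intronic points", {
  tus <- tu_set("t", "t", "chr1", 0L, 2000L, "+",
                list(cbind(c(0L, 1300L), c(300L, 2000L))))
  reads <- point_reads("chr1", c(100L, 500L, 1400L), "+", assay = "RNA")
  expect_equal(count_rna(tus, reads, "exonic")[1], 2L)
  expect_equal(count_rna(tus, reads, "intronic")[1], 1L)
  none <- point_reads(character(0), integer(0), character(0), "RNA")
  expect_equal(count_rna(tus, none, "exonic")[1], 0L)
  expect_equal(count_rna(tus, none, "intronic")[1], 0L)
  # intron-less TU: intronic count is not applicable
  nointron <- tu_set("u", "u", "chr1", 0L, 2000L, "+",
                     list(cbind(0L, 2000L)))
  expect_true(is.na(count_rna(nointron, reads, "intronic")[1]))
})

test_that("counting matches a brute-force membership oracle and is order-invariant", {
  set.seed(101)
  for (rep in 1:20) {
    n_tu <- 5L
    starts <- sort(sample.int(50000L, n_tu)) * 2L
    ends <- starts + sample(1500:4000, n_tu)
    strands <- sample(c("+", "-"), n_tu, replace = TRUE)
    # one exon covering a random sub-interval of each span
    exons <- lapply(seq_len(n_tu), function(i) {
      w <- ends[i] - starts[i]
      a <- starts[i] + sample.int(w %/% 3, 1L)
      b <- ends[i] - sample.int(w %/% 3, 1L)
      cbind(a, b)
    })
    tus <- tu_set(paste0("t", 1:n_tu), paste0("t", 1:n_tu), "chr1",
                  starts, ends, strands, exons)
    reads <- point_reads("chr1",
                         sample.int(max(tus$end) + 100L, 400L) - 1L,
                         sample(c("+", "-"), 400L, replace = TRUE))
    got <- count_pro(tus, reads, 200L, 300L)
    for (i in seq_len(n_tu)) {
      lo <- if (tus$strand[i] == "+") tus$start[i] + 200L else
        tus$start[i] + 300L
      hi <- if (tus$strand[i] == "+") tus$end[i] - 300L else
        tus$end[i] - 200L
      expect_identical(got[i],
                       brute_count(reads, "chr1", lo, hi, tus$strand[i]))
    }
    ex <- count_rna(tus, reads, "exonic")
    intr <- count_rna(tus, reads, "intronic")
    for (i in seq_len(n_tu)) {
      e <- tus$exons[[i]]
      expect_identical(ex[i], brute_count(reads, "chr1", e[1, 1], e[1, 2],
                                          tus$strand[i]))
      expect_identical(intr[i],
                       brute_count(reads, "chr1", tus$start[i], tus$end[i],
                                   tus$strand[i]) - ex[i])
    }
    shuf <- reads[sample.int(nrow(reads)), ]
    expect_identical(as.integer(count_pro(tus, shuf, 200L, 300L)),
                     as.integer(got))
  }
})

test_that("TPM normalizes rates to parts per million", {
  expect_equal(tpm(c(10, 20), c(1000, 2000)), c(5e5, 5e5))
  expect_equal(tpm(5, 1234), 1e6)
  expect_equal(tpm(c(1, 1, 2), c(100, 100, 100)), c(25e4, 25e4, 50e4))
  expect_equal(tpm(c(0, 0), c(10, 10)), c(0, 0))
  expect_error(tpm(c(1, 1), c(100, 0)), "effective length")
  set.seed(7)
  for (i in 1:10) {
    x <- tpm(rpois(50, 20), sample(500:5000, 50))
    expect_equal(sum(x), 1e6, tolerance = 1e-9)
  }
})

test_that("replicate pooling sums counts and reports rank concordance", {
  expect_equal(pool_replicates(cbind(3, 5), eff_len = 100)$pooled, 8)
  cm <- cbind(c(10, 20, 5), c(10, 20, 5))
  expect_equal(pool_replicates(cm, eff_len = c(1, 1, 1))$concordance, 1)
  set.seed(11)
  mu <- rgamma(200, 2, 0.05)
  a <- rpois(200, mu); b <- rpois(200, mu)
  got <- pool_replicates(cbind(a, b), eff_len = rep(1000, 200))$concordance
  # independent rank-correlation oracle (Pearson on ranks)
  ra <- rank(tpm(a, rep(1000, 200))); rb <- rank(tpm(b, rep(1000, 200)))
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_gt(got, 0); expect_lt(got, 1)
})

test_that("quantify assembles per-replicate and pooled TPMs coherently", {
  tus <- toy_tus()
  set.seed(5)
  pro <- lapply(1:2, function(j)
    point_reads("chr1", sample(1000:8999, 300, TRUE),
                sample(c("+", "-"), 300, TRUE)))
  rna <- lapply(1:2, function(j)
    point_reads("chr1", sample(1000:8999, 300, TRUE),
                sample(c("+", "-"), 300, TRUE), assay = "RNA"))
  q <- quantify(tus, pro, rna)
  expect_s3_class(q, "expression_set")
  expect_equal(q$pro_count_1 + q$pro_count_2,
               as.integer(count_pro(tus, pro[[1]])) +
                 as.integer(count_pro(tus, pro[[2]])))
  expect_equal(sum(q$pro_tpm, na.rm = TRUE), 1e6, tolerance = 1e-6)
  expect_equal(sum(q$rna_tpm, na.rm = TRUE), 1e6, tolerance = 1e-6)
  expect_equal(q$rna_eff_len, tus$mature_length)
  expect_equal(q$pro_eff_len, tus$end - tus$start)
  qb <- quantify(tus, pro, rna, pro_len = "body")
  expect_equal(qb$pro_eff_len, tus$end - tus$start - 1000L)
})
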