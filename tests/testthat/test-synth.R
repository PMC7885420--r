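test_that("simulate_tus returns valid structures and is seed-deterministic", {
  s1 <- simulate_tus(30, seed = 5)
  s2 <- simulate_tus(30, seed = 5)
  expect_equal(s1$tus, s2$tus)
  expect_equal(as.character(s1$genome[[1]]), as.character(s2$genome[[1]]))
  expect_false(isTRUE(all.equal(s1$tus,
                                simulate_tus(30, seed = 6)$tus)))
  tus <- s1$tus
  expect_s3_class(tus, "tu_set")
  expect_equal(nrow(tus), 30L)
  # spans meet the minimum (PRO body window stays non-degenerate)
  expect_true(all(tus$end - tus$start >= 2200L))
  # TUs are non-overlapping and ordered on the chromosome
  expect_true(all(tus$start[-1] >= tus$end[-30]))
  # exons inside spans, first starts at span start, last ends at span end
  for (i in 1:30) {
    e <- tus$exons[[i]]
    expect_equal(e[1, 1], tus$start[i], ignore_attr = TRUE)
    expect_equal(e[nrow(e), 2], tus$end[i], ignore_attr = TRUE)
  }
  # eRNAs are single-exon
  expect_true(all(vapply(tus$exons[tus$tu_class == "eRNA"], nrow,
                         integer(1)) == 1L))
  # CDS only for mRNAs, valid in mature coordinates
  expect_setequal(s1$cds$tu_id, tus$tu_id[tus$tu_class == "mRNA"])
  ml <- tus$mature_length[match(s1$cds$tu_id, tus$tu_id)]
  expect_true(all(s1$cds$cds_start >= 0 & s1$cds$cds_end <= ml &
                    s1$cds$cds_start < s1$cds$cds_end))
  # genome covers the layout
  expect_gte(length(s1$genome[[1]]), max(tus$end))
  # with_sequence = FALSE skips the genome but keeps identical structures
  s3 <- simulate_tus(30, seed = 5, with_sequence = FALSE)
  expect_null(s3$genome)
  expect_equal(s3$tus, s1$tus)
})

test_that("planted motifs appear at the configured sense-strand offsets", {
  cfg <- list(class_probs = c(mRNA = 1),
              plant = list(mRNA = list(u1 = 50, pas = 600)))
  s <- simulate_tus(12, seed = 9, config = cfg)
  ts <- tss_seq(s$tus, s$genome, span = 700L)
  expect_true(all(substr(ts, 51, 59) == U1_CONSENSUS))
  expect_true(all(substr(ts, 601, 606) == PAS_CONSENSUS))
  # both strands are represented, so planting survived orientation handling
  expect_setequal(unique(s$tus$strand), c("+", "-"))
})

test_that("gc gradient and composition controls reach the sequence", {
  s_hi <- simulate_tus(10, seed = 11, config = list(gc = 0.8))
  ts <- tss_seq(s_hi$tus, s_hi$genome, span = 1000L)
  expect_gt(mean(vapply(ts, gc_content, numeric(1))), 0.7)
  s_gr <- simulate_tus(10, seed = 11,
                       config = list(gc_gradient = c(0.8, 0.2)))
  tg <- tss_seq(s_gr$tus, s_gr$genome, span = 1000L)
  first <- mean(vapply(tg, function(x) gc_content(substr(x, 1, 200)),
                       numeric(1)))
  last <- mean(vapply(tg, function(x) gc_content(substr(x, 801, 1000)),
                      numeric(1)))
  expect_gt(first, last + 0.2)
})

test_that("mature_to_genomic inverts exon concatenation on both strands", {
  s <- simulate_tus(20, seed = 13)
  for (i in c(1, 5, 12, 20)) {
    tu <- s$tus[i, , drop = FALSE]
    ml <- tu$mature_length
    offs <- c(0L, as.integer(ml %/% 2), ml - 1L)
    g <- mature_to_genomic(tu, offs)
    # every genomic position is inside some exon
    e <- tu$exons[[1]]
    inside <- vapply(g, function(p) any(p >= e[, 1] & p < e[, 2]), logical(1))
    expect_true(all(inside))
    # base at the mature offset equals the mature sequence base
    mseq <- mature_seq(tu, s$genome)
    for (k in seq_along(offs)) {
      gb <- fetch_seq(s$genome, tu$chrom, g[k], g[k] + 1L, tu$strand)
      expect_equal(gb, substr(mseq, offs[k] + 1L, offs[k] + 1L))
    }
    expect_error(mature_to_genomic(tu, ml))  # out of range
  }
})

test_that("sem-mode expression reproduces the generative SEM exactly in law", {
  s <- simulate_tus(400, seed = 15, with_sequence = FALSE)
  X <- cbind(1, rnorm(400))
  sim <- simulate_expression(s$tus, X, lambda = c(2, 0.5), mu = c(1, -0.3),
                             sigmas = c(0.5, 0.4, 0.2, 0.2), mode = "sem",
                             seed = 21)
  expect_equal(sim$truth$m, sim$truth$b + sim$truth$t)
  expect_equal(sim$truth$half_life, exp(sim$truth$t))
  expect_equal(sim$truth$alpha, log(2) / sim$truth$half_life)
  expect_equal(dim(sim$p), c(400L, 2L))
  # residual structure: p - b has sd sigma_p, b - X lambda has sd sigma_b
  expect_equal(sd(sim$p[, 1] - sim$truth$b), 0.2, tolerance = 0.05)
  expect_equal(sd(sim$truth$b - X %*% c(2, 0.5)), 0.5, tolerance = 0.08)
  expect_equal(attr(sim$truth, "lambda"), c(2, 0.5))
  # deterministic under the seed
  sim2 <- simulate_expression(s$tus, X, c(2, 0.5), c(1, -0.3),
                              c(0.5, 0.4, 0.2, 0.2), mode = "sem", seed = 21)
  expect_equal(sim2$p, sim$p)
})

test_that("counts mode emits valid read sets proportional to the truth", {
  s <- simulate_tus(150, seed = 17, with_sequence = FALSE)
  X <- matrix(1, 150, 1)
  sim <- simulate_expression(s$tus, X, lambda = 3, mu = 1,
                             sigmas = c(0.8, 0.5, 0, 0), depth = 2e5,
                             mode = "counts", seed = 23)
  expect_length(sim$pro_reads, 2L)
  expect_equal(nrow(sim$pro_reads[[1]]), 2e5)
  pr <- sim$pro_reads[[1]]
  expect_true(all(pr$assay == "PRO"))
  # PRO reads fall inside the emitting TU's span on the right strand
  q <- quantify(s$tus, sim$pro_reads, sim$rna_reads)
  expect_equal(sum(q$pro_tpm, na.rm = TRUE), 1e6, tolerance = 1e-6)
  # RNA reads land only in exons: intronic counts are ~0
  intr <- count_rna(s$tus, do.call(rbind, sim$rna_reads), "intronic")
  expect_equal(sum(intr, na.rm = TRUE), 0L)
  # per-TU PRO read share tracks exp(b) * span
  pro_counts <- count_pro(s$tus, pr, 0L, 0L)
  w <- sim$truth$beta * (s$tus$end - s$tus$start)
  expect_gt(cor(pro_counts, w, method = "spearman"), 0.99)
  # elongation rates divide the PRO weights
  el <- runif(150, 0.5, 4)
  sim_el <- simulate_expression(s$tus, X, 3, 1, c(0.8, 0.5, 0, 0),
                                depth = 2e5, mode = "counts",
                                elongation = el, seed = 23)
  pe <- count_pro(s$tus, sim_el$pro_reads[[1]], 0L, 0L)
  expect_gt(cor(pe, w / el, method = "spearman"),
            cor(pe, w, method = "spearman"))
})
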