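test_that("RPKM identity holds and follows the defining formula", {
  exons <- data.frame(gene_id = "G", rank = 1L, chrom = "chr1",
                      start = 0L, end = 500L)
  counts <- matrix(c(10, 0), nrow = 1, dimnames = list(NULL, c("s1", "s2")))
  m <- exon_expression_matrix(exons, counts, total_reads = c(1e7, 1e7))
  # 10 reads / (0.5 kb * 10 M reads) = 2.0; zero reads -> zero RPKM
  expect_equal(unname(m$rpkm[1, "s1"]), 2.0)
  expect_equal(unname(m$rpkm[1, "s2"]), 0)
  expect_equal(m$rpkm, sweep(m$counts / m$length_kb, 2,
                             m$total_reads_millions, "/"),
               tolerance = 1e-9)
  expect_error(exon_expression_matrix(exons, counts, total_reads = c(0, 1e7)),
               "zero total reads")
})

test_that("alignment input counts only reads above the mapq cutoff", {
  sam <- write_toy_sam(tempfile(fileext = ".sam"))
  ann <- annotation_set(list(
    mk_gene("tx1", "chr1", "+", c(100, 300), c(200, 450), biotype = "noncoding")))
  m <- compute_exon_rpkm(list(s1 = sam), ann, min_mapq = 10L)
  # r1 and r2 overlap exon 1; r3 has mapq 5 and is excluded
  expect_equal(unname(m$counts[1, "s1"]), 2)
  m0 <- compute_exon_rpkm(list(s1 = sam), ann, min_mapq = 0L)
  expect_equal(unname(m0$counts[1, "s1"]), 3)
})

test_that("COPA trimmed estimators match the worked example", {
  m <- one_exon_matrix(c(1:9, 100))
  res <- copa_z(m, trim_fraction = 0.75)
  # k = ceiling(0.75 * 10) = 8; mu, sigma over the lowest 8 sorted values
  expect_equal(res$k, 8L)
  expect_equal(res$mu, 4.5)
  expect_equal(res$sigma, sd(1:8))
  expect_equal(unname(res$z[1, 10]), (100 - 4.5) / sd(1:8), tolerance = 1e-6)
  expect_equal(unname(res$z[1, 10]), 38.99, tolerance = 1e-2)
  expect_true(res$outlier[1, 10])
  expect_false(any(res$outlier[1, 1:9]))
})

test_that("constant exons and the strict z threshold behave as defined", {
  res <- copa_z(one_exon_matrix(rep(5, 8)))
  expect_true(all(res$z == 0))
  expect_false(any(res$outlier))
  # a z of exactly the threshold is not an outlier (strict >)
  m <- one_exon_matrix(c(1:9, 100))
  res4 <- copa_z(m, z_min = (100 - 4.5) / sd(1:8))
  expect_false(res4$outlier[1, 10])
  expect_error(copa_z(one_exon_matrix(c(1, 2, 3))), "insufficient samples")
})

test_that("COPA z is invariant under sample reordering and positive scaling", {
  set.seed(21)
  vals <- rlnorm(12, log(20), 0.4)
  m <- one_exon_matrix(vals)
  res <- copa_z(m)
  perm <- sample(12)
  res_p <- copa_z(one_exon_matrix(vals[perm],
                                  samples = sprintf("s%02d", seq_len(12))))
  expect_equal(unname(res_p$z[1, ]), unname(res$z[1, perm]))
  res_s <- copa_z(one_exon_matrix(vals * 7))
  expect_equal(res_s$mu, res$mu * 7)
  expect_equal(res_s$sigma, res$sigma * 7)
  expect_equal(res_s$z, res$z, tolerance = 1e-12)
})

test_that("candidate selection equals a brute-force double loop", {
  set.seed(33)
  rpkm <- matrix(rlnorm(60, log(15), 0.6), nrow = 6,
                 dimnames = list(NULL, sprintf("s%02d", 1:10)))
  rpkm[2, 4] <- 400  # planted outlier above the floor
  exons <- data.frame(gene_id = rep(c("G1", "G2"), each = 3),
                      rank = rep(1:3, 2), chrom = "chr1",
                      start = (0:5) * 2000L, end = (0:5) * 2000L + 1000L)
  m <- exon_expression_matrix(exons, rpkm, total_reads = rep(1e6, 10))
  copa <- copa_z(m)
  got <- select_candidate_genes(copa, m, rpkm_min = 20)
  want <- unique(do.call(rbind, lapply(seq_len(nrow(rpkm)), function(i) {
    hits <- which(copa$outlier[i, ] & max(m$rpkm[i, ]) > 20)
    if (!length(hits)) return(NULL)
    data.frame(gene_id = exons$gene_id[i], sample = colnames(rpkm)[hits])
  })))
  want <- want[order(want$gene_id, want$sample), ]
  rownames(want) <- NULL
  expect_equal(got, want)
  # the threshold is strict: a gene peaking exactly at the floor is excluded
  m2 <- one_exon_matrix(c(rep(20, 9), 20))
  expect_equal(nrow(select_candidate_genes(copa_z(m2), m2, rpkm_min = 20)), 0L)
})

test_that("exon walking flags two-fold changes in normalized profiles", {
  # flat profile: no candidates
  flat <- matrix(10, nrow = 4, ncol = 8,
                 dimnames = list(NULL, sprintf("s%d", 1:8)))
  mf <- gene_profile_matrix(flat)
  expect_equal(nrow(walk_breakpoints(mf, "G", "s1")), 0L)

  # baseline 10 everywhere, sample s1 drops from 10 to 0.1 after rank 2:
  # normalized profile [1, 1, 0.01, 0.01] -> one drop at boundary (2,3)
  prof <- matrix(10, nrow = 4, ncol = 8,
                 dimnames = list(NULL, sprintf("s%d", 1:8)))
  prof[, 1] <- c(10, 10, 0.1, 0.1)
  mp <- gene_profile_matrix(prof)
  bp <- walk_breakpoints(mp, "G", "s1")
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$rank5, 2L)
  expect_equal(bp$rank3, 3L)
  expect_equal(bp$direction, "drop")
  expect_gte(bp$fold_change, 2)
})

test_that("a 40-exon gene with a planted drop after exon 34 is recovered", {
  n_ex <- 40L
  prof <- matrix(10, nrow = n_ex, ncol = 10,
                 dimnames = list(NULL, sprintf("s%02d", 1:10)))
  prof[1:34, 1] <- 80   # 5' overexpression up to exon 34, baseline after
  m <- gene_profile_matrix(prof)
  bp <- walk_breakpoints(m, "G", "s01")
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$rank5, 34L)
  expect_equal(bp$rank3, 35L)
  expect_equal(bp$direction, "drop")
})

test_that("walk output only depends on the sample profile and denominators", {
  set.seed(44)
  prof <- matrix(rlnorm(40, log(10), 0.2), nrow = 5, ncol = 8,
                 dimnames = list(NULL, sprintf("s%d", 1:8)))
  prof[1:2, 3] <- prof[1:2, 3] * 10
  m1 <- gene_profile_matrix(prof)
  # permuting the other samples leaves the per-exon 70th percentiles intact
  perm <- c(3, sample(setdiff(1:8, 3)))
  m2 <- gene_profile_matrix(prof[, perm])
  colnames(m2$rpkm)
  b1 <- walk_breakpoints(m1, "G", "s3")
  b2 <- walk_breakpoints(m2, "G", "s3")
  expect_equal(b1[, c("rank5", "rank3", "direction", "fold_change")],
               b2[, c("rank5", "rank3", "direction", "fold_change")])
})

test_that("silent exons borrow the smallest positive denominator", {
  prof <- matrix(c(rep(10, 8), rep(0, 8), rep(20, 8)), nrow = 3,
                 byrow = TRUE, dimnames = list(NULL, sprintf("s%d", 1:8)))
  m <- gene_profile_matrix(prof)
  wp <- walk_profile(m, "G", "s1")
  expect_equal(wp$q[2], min(wp$q[wp$q > 0]))
  # a gene silent everywhere is skipped
  m0 <- gene_profile_matrix(matrix(0, nrow = 3, ncol = 8,
                                   dimnames = list(NULL, sprintf("s%d", 1:8))))
  expect_null(walk_profile(m0, "G", "s1"))
})
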