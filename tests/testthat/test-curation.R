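test_that("caller dialect readers parse their layouts", {
  pot <- tempfile()
  writeLines(c("s1\tchr1-chr2\t100\t200\tff\t40\t2",
               "s1\tchr1-chr1\t500\t900\tfr\t12\t0",
               "s2\tchr3-chr4\t77\t88\trr\t9\t1"), pot)
  recs <- read_caller_records(pot, "tophatfusion_potential")
  expect_equal(nrow(recs), 3L)
  expect_true(all(recs$candidate_only))
  expect_true(all(is.na(recs$gene5)))
  expect_equal(recs$chrom3[1], "chr2")
  expect_equal(recs$orient3[2], "r")

  ss <- tempfile()
  # two isoforms of the same gene pair stay distinct records
  writeLines(c("s1\tGA\tchr1\t100\t+\tGB\tchr1\t900\t+\t25\t1",
               "s1\tGA\tchr1\t100\t+\tGB\tchr1\t1200\t+\t11\t2"), ss)
  srecs <- read_caller_records(ss, "snowshoes")
  expect_equal(nrow(srecs), 2L)
  expect_equal(srecs$caller, rep("snowshoes", 2))

  bad <- tempfile()
  writeLines("s1\tonly\tthree", bad)
  expect_error(read_caller_records(bad, "snowshoes"), "dialect error")
})

test_that("records in both caller files are reconciled as non-candidate-only", {
  pot <- tempfile(); res <- tempfile()
  writeLines(c("s1\tchr1-chr2\t100\t200\tff\t40\t2",
               "s1\tchr1-chr1\t500\t900\tfr\t12\t0"), pot)
  writeLines("s1\tGA\tchr1\t100\tGB\tchr2\t200\t45\t2\tff", res)
  merged <- merge_caller_records(list(
    read_caller_records(pot, "tophatfusion_potential"),
    read_caller_records(res, "tophatfusion_result")))
  expect_equal(nrow(merged), 2L)
  m1 <- merged[merged$pos5 == 100, ]
  expect_false(m1$candidate_only)
  expect_equal(m1$gene5, "GA")
  expect_equal(m1$span_reads, 45)  # max over sources
  m2 <- merged[merged$pos5 == 500, ]
  expect_true(m2$candidate_only)
})

test_that("merging collapses duplicates within tolerance and keeps the rest", {
  set.seed(12)
  n <- 30L
  # base records at well-separated coordinates so only cross-source
  # duplicates can ever match
  base <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(sample = "s1", gene5 = paste0("g", i), gene3 = paste0("h", i),
               chrom5 = "chr1", pos5 = 1000 * i, strand5 = NA_character_,
               chrom3 = "chr2", pos3 = 1000 * i + 57, strand3 = NA_character_,
               orient5 = "f", orient3 = "f", span_reads = 10 + i,
               span_pairs = NA_real_, caller = "a", candidate_only = FALSE,
               stringsAsFactors = FALSE)
  }))
  dup <- base[1:12, ]
  jitter <- c(rep(3, 8), rep(400, 4))  # 8 within tol, 4 beyond
  dup$pos5 <- dup$pos5 + jitter
  dup$pos3 <- dup$pos3 - jitter
  dup$caller <- "b"
  dup$span_reads <- dup$span_reads + 100
  merged <- merge_caller_records(list(base, dup), tol = 10L)
  expect_equal(nrow(merged), n + 4L)
  hit <- merged[merged$gene5 == "g1", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$caller, "a,b")
  expect_equal(hit$span_reads, 111)  # max over sources
  far <- merged[merged$gene5 == "g9", ]
  expect_equal(nrow(far), 2L)  # beyond tolerance stays distinct
})

test_that("the curation filter matches the brute-force rule evaluator", {
  sim <- get_sim(1)
  ann <- sim$reference$annotation
  copa <- copa_z(sim$data$matrix)
  params <- curation_params(boundary_tol = 5L)
  recs <- random_records(1000, ann, colnames(copa$z), seed = 99)
  wt <- data.frame(wt5 = sample(c(NA, 0:60), 1000, replace = TRUE),
                   wt3 = sample(c(NA, 0:60), 1000, replace = TRUE))
  out <- apply_curation(recs, ann, copa, wt, params)
  expect_equal(nrow(out), 1000L)  # audit conservation
  want <- brute_curation(recs, ann, copa, wt, params)
  expect_identical(out$retained, want)
})

test_that("retention is monotone under threshold tightening", {
  sim <- get_sim(1)
  ann <- sim$reference$annotation
  copa <- copa_z(sim$data$matrix)
  recs <- random_records(300, ann, colnames(copa$z), seed = 7)
  wt <- data.frame(wt5 = sample(c(NA, 0:60), 300, replace = TRUE),
                   wt3 = sample(c(NA, 0:60), 300, replace = TRUE))
  loose <- apply_curation(recs, ann, copa, wt, curation_params(boundary_tol = 10L))
  for (p in list(curation_params(min_ratio = 4, boundary_tol = 10L),
                 curation_params(min_span = 180, boundary_tol = 10L),
                 curation_params(z_pass = 9, boundary_tol = 10L),
                 curation_params(z_candidate_only = 20, boundary_tol = 10L),
                 curation_params(boundary_tol = 0L))) {
    tight <- apply_curation(recs, ann, copa, wt, p)
    expect_true(all(!tight$retained | loose$retained))
  }
})

test_that("published support counts pass the ratio rule; blacklist rejects", {
  ann <- toy_annotation()
  b <- ann$boundaries[1, ]
  mk_rec <- function(gene5, gene3, span) {
    data.frame(sample = "s1", gene5 = gene5, gene3 = gene3,
               chrom5 = b$chrom, pos5 = b$end1, strand5 = NA,
               chrom3 = b$chrom, pos3 = b$start1, strand3 = NA,
               orient5 = NA, orient3 = NA, span_reads = span,
               span_pairs = NA, caller = "t", candidate_only = FALSE,
               stringsAsFactors = FALSE)
  }
  # junction reads 47 vs wild-type (6, 3): 47/6 > 2 passes the ratio rule
  out <- apply_curation(mk_rec("MON2", "MARS", 47), ann, NULL,
                        data.frame(wt5 = 6, wt3 = 3), curation_params())
  expect_true(out$rule2_ratio)
  # wild-type count 0 passes outright (the published FGFR3-TACC3 case)
  out0 <- apply_curation(mk_rec("FGFR3", "TACC3", 13), ann, NULL,
                         data.frame(wt5 = 31, wt3 = 0), curation_params())
  expect_true(out0$rule2_ratio)
  # a ratio below 2 on both sides fails
  lo <- apply_curation(mk_rec("X", "Y", 40), ann, NULL,
                       data.frame(wt5 = 30, wt3 = 25), curation_params())
  expect_false(lo$rule2_ratio)
  # the normal-tissue pair is rejected by the blacklist whatever its support
  bl <- apply_curation(mk_rec("TFG", "GPR128", 500), ann, NULL,
                       data.frame(wt5 = 0, wt3 = 0), curation_params())
  expect_false(bl$rule6_blacklist)
  expect_false(bl$retained)
})

test_that("candidate-only records need the stronger outlier evidence", {
  sim <- get_sim(1)
  ann <- sim$reference$annotation
  copa <- copa_z(sim$data$matrix)
  tr <- sim$planted$truth[1, ]  # fused gene: z far above 10 in its sample
  mk <- function(co, gene5, sample) {
    data.frame(sample = sample, gene5 = gene5, gene3 = "UAR",
               chrom5 = tr$chrom5, pos5 = tr$pos5, strand5 = NA,
               chrom3 = tr$chrom3, pos3 = tr$pos3, strand3 = NA,
               orient5 = NA, orient3 = NA, span_reads = 50,
               span_pairs = NA, caller = "t", candidate_only = co,
               stringsAsFactors = FALSE)
  }
  wt <- data.frame(wt5 = 0, wt3 = NA)
  # fused gene in the fused sample: z >> 10 -> retained even candidate-only
  hi <- apply_curation(mk(TRUE, tr$gene5, tr$sample), ann, copa, wt,
                       curation_params())
  expect_true(hi$rule4_candidate_only)
  # same record in a background sample: z below 10 -> rejected
  lo <- apply_curation(mk(TRUE, tr$gene5, "S20"), ann, copa, wt,
                       curation_params())
  expect_false(lo$rule4_candidate_only)
  expect_false(lo$retained)
  # not candidate-only: rule 4 does not apply
  off <- apply_curation(mk(FALSE, tr$gene5, "S20"), ann, copa, wt,
                        curation_params())
  expect_true(off$rule4_candidate_only)
})
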