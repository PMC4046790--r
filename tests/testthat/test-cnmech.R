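seg_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample = "s1", chrom = r[[1]], start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), n_markers = NA_integer_,
               seg_mean = as.numeric(r[[4]]))
  }))
}

test_that("SEG reading extracts endpoints and rejects overlaps", {
  path <- tempfile(fileext = ".seg")
  df <- seg_df(list("chr1", 1, 1000, 0.1), list("chr1", 1001, 5000, 1.2))
  names(df) <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- read_segments(path)
  expect_s3_class(ss, "SegmentSet")
  expect_equal(nrow(ss$breakpoints), 4L)
  expect_setequal(ss$breakpoints$pos, c(1, 1000, 1001, 5000))
  # gzip input gives the identical result
  gz <- paste0(tempfile(), ".seg.gz")
  con <- gzfile(gz, "w"); write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE); close(con)
  expect_equal(read_segments(gz)$segments, ss$segments)
  # overlap is a hard error
  expect_error(segment_set(seg_df(list("chr1", 1, 1000, 0),
                                  list("chr1", 900, 2000, 1))),
               "overlapping segments")
})

test_that("endpoint extraction equals a brute-force scan on random segments", {
  set.seed(17)
  starts <- sort(sample(1:1e6, 100))
  ends <- starts + sample(100:5000, 100, replace = TRUE)
  ok <- c(TRUE, ends[-100] < starts[-1])
  df <- data.frame(sample = "s1", chrom = "chr1", start = starts[ok],
                   end = ends[ok], seg_mean = rnorm(sum(ok)))
  ss <- segment_set(df)
  expect_setequal(ss$breakpoints$pos, unique(c(df$start, df$end)))
})

test_that("nearest breakpoint distances match a linear scan", {
  ss <- segment_set(seg_df(list("chr1", 1000, 1999, 0),
                           list("chr1", 2000, 5000, 1)))
  expect_equal(nearest_breakpoint(1000, "chr1", ss), 0)
  expect_equal(nearest_breakpoint(1500, "chr1", ss), 499)  # midway-ish
  expect_equal(nearest_breakpoint(10, "chr2", ss), Inf)
  set.seed(4)
  bps <- c(1000, 1999, 2000, 5000)
  for (pos in sample(1:6000, 50)) {
    expect_equal(nearest_breakpoint(pos, "chr1", ss), min(abs(bps - pos)))
  }
})

test_that("the mechanism decision tree labels constructed profiles", {
  w <- 30000
  # focal amplification: both points interior to one amplified segment
  amp <- segment_set(seg_df(list("chr1", 1, 99999, 0),
                            list("chr1", 100000, 300000, 2.0),
                            list("chr1", 300001, 400000, 0)))
  f <- list(chrom5 = "chr1", pos5 = 170000, chrom3 = "chr1", pos3 = 210000)
  expect_equal(classify_mechanism(f, amp)$label, "focal_amplification")

  # tandem duplication: 5' point at the amplified segment's end, 3' at start
  td <- list(chrom5 = "chr1", pos5 = 300000, chrom3 = "chr1", pos3 = 100000)
  expect_equal(classify_mechanism(td, amp)$label, "tandem_duplication")

  # deletion: points flank a low segment between two higher neighbors
  del <- segment_set(seg_df(list("chr1", 1, 99999, 0.5),
                            list("chr1", 100000, 200000, -0.7),
                            list("chr1", 200001, 400000, 0.5)))
  fd <- list(chrom5 = "chr1", pos5 = 100000, chrom3 = "chr1", pos3 = 200000)
  expect_equal(classify_mechanism(fd, del)$label, "deletion_based")

  # complex: matched breakpoints with more than one whole segment between
  cx <- segment_set(seg_df(list("chr1", 1, 99999, 0),
                           list("chr1", 100000, 140000, 1.5),
                           list("chr1", 140001, 200000, -0.5),
                           list("chr1", 200001, 260000, 1.2),
                           list("chr1", 260001, 300000, -0.3),
                           list("chr1", 300001, 400000, 0)))
  fc <- list(chrom5 = "chr1", pos5 = 100000, chrom3 = "chr1", pos3 = 300000)
  expect_equal(classify_mechanism(fc, cx)$label, "complex")

  # interchromosomal: different chromosomes, one point at a segment end
  ic <- segment_set(seg_df(list("chr1", 1, 99999, 0.8),
                           list("chr1", 100000, 400000, 0),
                           list("chr2", 1, 400000, 0)))
  fi <- list(chrom5 = "chr1", pos5 = 99999, chrom3 = "chr2", pos3 = 200000)
  expect_equal(classify_mechanism(fi, ic)$label, "interchromosomal")
  # and no breakpoint near either point on different chromosomes -> none
  fi2 <- list(chrom5 = "chr1", pos5 = 250000, chrom3 = "chr2", pos3 = 200000)
  expect_equal(classify_mechanism(fi2, ic)$label, "none")

  # flat profile: no breakpoints near the points -> none
  flat <- segment_set(seg_df(list("chr1", 1, 400000, 0)))
  fn <- list(chrom5 = "chr1", pos5 = 150000, chrom3 = "chr1", pos3 = 250000)
  expect_equal(classify_mechanism(fn, flat)$label, "none")
})

test_that("planted mechanism profiles are recovered 6/6 and shift-invariant", {
  sim <- get_sim(1)
  tr <- sim$planted$truth
  got <- vapply(seq_len(nrow(tr)), function(i) {
    classify_mechanism(tr[i, ], sim$planted$segsets[[tr$sample[i]]])$label
  }, character(1))
  expect_identical(got, tr$mechanism)
  expect_setequal(unique(got),
                  c("focal_amplification", "complex", "tandem_duplication",
                    "interchromosomal", "deletion_based", "none"))
  # shifting every coordinate by a constant leaves the labels unchanged
  shift <- 12345
  for (i in seq_len(nrow(tr))) {
    ss <- sim$planted$segsets[[tr$sample[i]]]
    segs <- ss$segments
    segs$start <- segs$start + shift
    segs$end <- segs$end + shift
    ss2 <- segment_set(segs)
    f2 <- tr[i, ]
    f2$pos5 <- f2$pos5 + shift
    f2$pos3 <- f2$pos3 + shift
    expect_equal(classify_mechanism(f2, ss2)$label, tr$mechanism[i])
  }
})

test_that("partner copy-number correlation follows the textbook formula", {
  mk_segs <- function(vals5, vals3) {
    lapply(seq_along(vals5), function(i) {
      segment_set(seg_df(list("chr1", 1, 200000, vals5[i]),
                         list("chr1", 200001, 400000, vals3[i])))
    })
  }
  fus <- data.frame(sample = paste0("p", 1:4), chrom5 = "chr1", pos5 = 100000,
                    chrom3 = "chr1", pos3 = 300000)
  # identical values at both points -> r = 1
  segs <- mk_segs(c(1, 2, 3, 4), c(1, 2, 3, 4))
  names(segs) <- fus$sample
  expect_equal(partner_copy_correlation(fus, segs), 1)
  # antisymmetric pairs -> r = -1
  segs2 <- mk_segs(c(1, 2, 3, 4), c(4, 3, 2, 1))
  names(segs2) <- fus$sample
  expect_equal(partner_copy_correlation(fus, segs2), -1)
  # random pairs match cor()
  set.seed(8)
  a <- rnorm(6); b <- rnorm(6)
  fus6 <- data.frame(sample = paste0("q", 1:6), chrom5 = "chr1", pos5 = 100000,
                     chrom3 = "chr1", pos3 = 300000)
  segs3 <- mk_segs(a, b)
  names(segs3) <- fus6$sample
  expect_equal(partner_copy_correlation(fus6, segs3), cor(a, b))
  expect_error(partner_copy_correlation(fus6[1:2, ], segs3[1:2]), ">= 3")
})
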