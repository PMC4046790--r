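# Independent brute-force evaluator of the six curation rules plus the
# adjacency discard, coded directly from their written definitions.
brute_curation <- function(records, ann, copa, wt, params) {
  b <- ann$boundaries
  bounds <- data.frame(chrom = c(b$chrom, b$chrom), pos = c(b$start1, b$end1))
  sym_of <- vapply(ann$genes, `[[`, character(1), "symbol")
  strand_of <- vapply(ann$genes, `[[`, character(1), "strand")
  spans <- t(vapply(ann$genes, gene_span, numeric(2)))
  chrom_of <- vapply(ann$genes, `[[`, character(1), "chrom")

  vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    near <- function(chrom, pos) {
      any(bounds$chrom == chrom & abs(bounds$pos - pos) <= params$boundary_tol)
    }
    r1 <- near(r$chrom5, r$pos5) || near(r$chrom3, r$pos3)
    rp <- function(wtv) is.na(wtv) || wtv == 0 || r$span_reads / wtv > params$min_ratio
    r2 <- rp(wt$wt5[i]) || rp(wt$wt3[i])
    zmax <- -Inf
    for (g in c(r$gene5, r$gene3)) {
      if (is.na(g) || g == "UAR") next
      ids <- names(sym_of)[sym_of == g]
      rows <- which(copa$exons$gene_id %in% ids)
      if (length(rows) && r$sample %in% colnames(copa$z)) {
        zmax <- max(zmax, copa$z[rows, r$sample])
      }
    }
    r3 <- r$span_reads >= params$min_span || zmax >= params$z_pass
    r4 <- !isTRUE(r$candidate_only) || zmax >= params$z_candidate_only
    ok_side <- function(g, o) {
      if (is.na(g) || g == "UAR" || is.na(o) || !g %in% sym_of) return(TRUE)
      st <- strand_of[match(g, sym_of)]
      (st == "+") == (o == "f")
    }
    r5 <- ok_side(r$gene5, r$orient5) && ok_side(r$gene3, r$orient3)
    r6 <- !any(!is.na(r$gene5) & !is.na(r$gene3) &
               params$blacklist$gene5 == r$gene5 &
               params$blacklist$gene3 == r$gene3)
    adj <- TRUE
    if (!is.na(r$gene5) && !is.na(r$gene3) &&
        r$gene5 %in% sym_of && r$gene3 %in% sym_of && r$gene5 != r$gene3) {
      i5 <- match(r$gene5, sym_of); i3 <- match(r$gene3, sym_of)
      if (chrom_of[i5] == chrom_of[i3]) {
        gap <- c(min(spans[i5, 2], spans[i3, 2]), max(spans[i5, 1], spans[i3, 1]))
        neighbors <- gap[1] >= gap[2]
        if (!neighbors) {
          neighbors <- !any(vapply(seq_along(sym_of), function(k) {
            k != i5 && k != i3 && chrom_of[k] == chrom_of[i5] &&
              spans[k, 1] >= gap[1] && spans[k, 2] <= gap[2]
          }, logical(1)))
        }
        adj <- !neighbors
      }
    }
    r1 && r2 && r3 && r4 && r5 && r6 && adj
  }, logical(1))
}

random_records <- function(n, ann, samples, seed) {
  set.seed(seed)
  syms <- vapply(ann$genes, `[[`, character(1), "symbol")
  b <- ann$boundaries
  all_bounds <- data.frame(chrom = c(b$chrom, b$chrom),
                           pos = c(b$start1, b$end1),
                           gene = c(b$gene_id, b$gene_id))
  pick_pos <- function() {
    i <- sample(nrow(all_bounds), 1)
    off <- sample(c(0L, 0L, 0L, sample(1:500, 1)), 1)
    list(chrom = all_bounds$chrom[i], pos = all_bounds$pos[i] + off)
  }
  recs <- lapply(seq_len(n), function(i) {
    p5 <- pick_pos(); p3 <- pick_pos()
    g5 <- sample(c(unname(syms), "TFG", NA), 1)
    g3 <- sample(c(unname(syms), "UAR", "GPR128", NA), 1)
    data.frame(sample = sample(samples, 1), gene5 = g5, gene3 = g3,
               chrom5 = p5$chrom, pos5 = p5$pos, strand5 = NA_character_,
               chrom3 = p3$chrom, pos3 = p3$pos, strand3 = NA_character_,
               orient5 = sample(c("f", "r", NA), 1),
               orient3 = sample(c("f", "r", NA), 1),
               span_reads = sample(0:200, 1), span_pairs = NA_real_,
               caller = "random", candidate_only = sample(c(TRUE, FALSE), 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

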