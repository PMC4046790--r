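# Shared fixtures: memoized simulated cohorts and small hand-built
# annotations / files, all generated in code at test time.

.sim_env <- new.env(parent = emptyenv())

get_sim <- function(seed = 1L, error_rate = 0) {
  key <- paste0("s", seed, "_e", error_rate)
  if (is.null(.sim_env[[key]])) {
    .sim_env[[key]] <- simulate_cohort(sim_config(seed = seed,
                                                  error_rate = error_rate))
  }
  .sim_env[[key]]
}

mk_gene <- function(id, chrom, strand, starts, ends, cds = NULL,
                    biotype = "coding", symbol = id, sources = "test") {
  gene_model(id, symbol, chrom, strand,
             data.frame(start = starts, end = ends),
             cds_span = cds, biotype = biotype, sources = sources)
}

# chr1: three well-separated 2-exon genes (A, B, C left to right); chr2: D
toy_annotation <- function() {
  annotation_set(list(
    mk_gene("A", "chr1", "+", c(100, 300), c(200, 450), cds = c(30, 230)),
    mk_gene("B", "chr1", "+", c(1000, 1250), c(1120, 1400), cds = c(12, 200)),
    mk_gene("C", "chr1", "-", c(2300, 2000), c(2600, 2150), cds = c(21, 300)),
    mk_gene("D", "chr2", "+", c(500, 900), c(700, 1100), cds = c(33, 330))
  ))
}

# write gene models as a minimal GTF (exon + CDS-less) for parser tests
write_toy_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    for (i in seq_len(nrow(g$exons))) {
      lines <- c(lines, paste(
        g$chrom, "test", "exon",
        g$exons$start[i] + 1L, g$exons$end[i], ".", g$strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                g$symbol, g$gene_id, g$symbol),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  path
}

# a tiny SAM file: three mapped reads on chr1, one below mapq 10
write_toy_sam <- function(path) {
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:2000",
    paste("r1", 0, "chr1", 101, 60, "50M", "*", 0, 0,
          paste(rep("A", 50), collapse = ""), "*", sep = "\t"),
    paste("r2", 0, "chr1", 120, 60, "50M", "*", 0, 0,
          paste(rep("A", 50), collapse = ""), "*", sep = "\t"),
    paste("r3", 0, "chr1", 130, 5, "50M", "*", 0, 0,
          paste(rep("A", 50), collapse = ""), "*", sep = "\t"))
  writeLines(lines, path)
  path
}

# expression matrix with a single exon whose RPKM values are given directly
# (exon length 1 kb, library 1 M reads, so RPKM == count)
one_exon_matrix <- function(values, gene_id = "G", samples = NULL) {
  if (is.null(samples)) samples <- sprintf("s%02d", seq_along(values))
  exons <- data.frame(gene_id = gene_id, rank = 1L, chrom = "chr1",
                      start = 0L, end = 1000L)
  counts <- matrix(values, nrow = 1, dimnames = list(NULL, samples))
  exon_expression_matrix(exons, counts, total_reads = rep(1e6, length(values)))
}

# matrix for one gene with given per-rank, per-sample RPKM values
gene_profile_matrix <- function(rpkm, gene_id = "G") {
  n_ex <- nrow(rpkm)
  samples <- colnames(rpkm)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(rpkm)))
  exons <- data.frame(gene_id = gene_id, rank = seq_len(n_ex), chrom = "chr1",
                      start = (seq_len(n_ex) - 1L) * 2000L,
                      end = (seq_len(n_ex) - 1L) * 2000L + 1000L)
  counts <- matrix(rpkm, nrow = n_ex, dimnames = list(NULL, samples))
  exon_expression_matrix(exons, counts, total_reads = rep(1e6, ncol(rpkm)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
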