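# ---------------------------------------------------------------------------
# Exon-level RPKM, modified COPA outlier z-scores, and exon walking.
# ---------------------------------------------------------------------------

#' Construct an exon expression matrix
#'
#' Holds per-exon raw counts, exon lengths, per-sample library sizes and the
#' derived RPKM values; the identity
#' `rpkm = count / (length_kb * total_reads_millions)` holds for every cell.
#'
#' @param exons data.frame with columns `gene_id`, `rank`, `chrom`, `start`,
#'   `end` (0-based half-open genomic coordinates).
#' @param counts Numeric matrix (exons x samples) of non-negative raw counts.
#' @param total_reads Per-sample total mapped reads (raw read counts, not
#'   millions); all must be positive.
#' @return An `ExonExpressionMatrix` with elements `exons`, `counts`,
#'   `rpkm`, `total_reads_millions`, `length_kb`, `samples`.
#' @export
exon_expression_matrix <- function(exons, counts, total_reads) {
  stopifnot(is.data.frame(exons),
            all(c("gene_id", "rank", "chrom", "start", "end") %in% names(exons)),
            nrow(exons) == nrow(counts))
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  if (any(counts < 0)) stop("negative counts")
  if (length(total_reads) != ncol(counts)) {
    stop("total_reads must have one entry per sample")
  }
  if (any(total_reads <= 0)) stop("sample with zero total reads")
  len_kb <- (exons$end - exons$start) / 1000
  if (any(len_kb <= 0)) stop("exon of zero length")
  tm <- total_reads / 1e6
  rpkm <- sweep(counts / len_kb, 2, tm, "/")
  rownames(rpkm) <- rownames(counts) <- paste(exons$gene_id, exons$rank, sep = ":")
  structure(list(exons = exons, counts = counts, rpkm = rpkm,
                 total_reads_millions = setNames(tm, colnames(counts)),
                 length_kb = len_kb, samples = colnames(counts)),
            class = "ExonExpressionMatrix")
}

#' @export
print.ExonExpressionMatrix <- function(x, ...) {
  cat("ExonExpressionMatrix:", nrow(x$rpkm), "exons x", ncol(x$rpkm), "samples\n")
  invisible(x)
}

#' Compute exon-level RPKM from alignments or a count table
#'
#' With a SAM/BAM input, a read is counted for every exon it overlaps by at
#' least one base, provided its mapping quality is at least `min_mapq`
#' (default 10). With a count table input the counts are used as given.
#'
#' @param input Either a named list of SAM/BAM paths (one per sample), or a
#'   data.frame in per-exon count TSV layout: columns `gene_id`, `rank`,
#'   `chrom`, `start`, `end` followed by one column per sample.
#' @param annotation An `AnnotationSet`; every `gene_id` must resolve.
#' @param min_mapq Minimum mapping quality for alignment input.
#' @param total_reads Optional per-sample library sizes; for alignment input
#'   the default is the number of mapq-passing alignments in each file.
#' @return An `ExonExpressionMatrix`.
#' @export
compute_exon_rpkm <- function(input, annotation, min_mapq = 10L,
                              total_reads = NULL) {
  if (is.data.frame(input)) {
    meta_cols <- c("gene_id", "rank", "chrom", "start", "end")
    stopifnot(all(meta_cols %in% names(input)))
    sample_cols <- setdiff(names(input), meta_cols)
    if (!length(sample_cols)) stop("no sample columns in count table")
    exons <- input[, meta_cols]
    counts <- as.matrix(input[, sample_cols, drop = FALSE])
    if (is.null(total_reads)) total_reads <- colSums(counts)
  } else if (is.list(input)) {
    exons <- .annotation_exon_table(annotation)
    exon_gr <- GRanges(exons$chrom, IRanges(exons$start + 1L, exons$end))
    counts <- matrix(0, nrow(exons), length(input),
                     dimnames = list(NULL, names(input)))
    observed_totals <- numeric(length(input))
    for (i in seq_along(input)) {
      ga <- .read_alignments(input[[i]], min_mapq)
      observed_totals[i] <- length(ga)
      counts[, i] <- countOverlaps(exon_gr, ga, minoverlap = 1L)
    }
    if (is.null(total_reads)) total_reads <- observed_totals
  } else {
    stop("input must be a count data.frame or a named list of SAM/BAM paths")
  }
  missing <- setdiff(unique(exons$gene_id), names(annotation$genes))
  if (length(missing)) {
    stop("gene_id(s) not in annotation: ", paste(head(missing, 5), collapse = ", "))
  }
  exon_expression_matrix(exons, counts, total_reads)
}

.annotation_exon_table <- function(annotation) {
  do.call(rbind, lapply(annotation$genes, function(m) {
    data.frame(gene_id = m$gene_id, rank = m$exons$rank, chrom = m$chrom,
               start = m$exons$start, end = m$exons$end,
               stringsAsFactors = FALSE)
  }))
}

.read_alignments <- function(path, min_mapq) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(mapqFilter = min_mapq))
  GenomicRanges::granges(ga)
}

#' Read a per-exon count TSV
#'
#' Layout: `gene_id`, `rank`, `chrom`, `start`, `end`, then one column per
#' sample; gzip accepted.
#' @param path File path.
#' @export
read_exon_counts <- function(path) {
  read.delim(if (grepl("\\.gz$", path)) gzfile(path) else path,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an RPKM matrix as TSV
#' @param matrix An `ExonExpressionMatrix`.
#' @param path Output path.
#' @export
write_rpkm_matrix <- function(matrix, path) {
  out <- cbind(matrix$exons, as.data.frame(matrix$rpkm, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Modified COPA outlier z-scores per exon
#'
#' For each exon, RPKM values are sorted ascending and the trimmed center and
#' spread are computed over the lowest `k = ceiling(trim_fraction * n)`
#' values (standard deviation with the n-1 denominator over those k values).
#' Excluding the high tail lets an outlier sample inflate its own z-score,
#' which is the point of the cancer-outlier statistic: z = (x - mu) / sigma.
#' Exons with trimmed sigma below `eps` get z = 0 everywhere (constant
#' exons carry no outlier signal). An exon x sample cell is flagged an
#' outlier when z is strictly greater than `z_min`.
#'
#' @param matrix An `ExonExpressionMatrix` (needs >= 4 samples).
#' @param trim_fraction Fraction f of samples in the trimmed estimators,
#'   0 < f <= 1 (default 0.75).
#' @param z_min Outlier threshold on z (strict >; default 4).
#' @param eps Floor on the trimmed standard deviation (default 1e-8).
#' @return A `CopaResult`: `z` matrix, logical `outlier` matrix, per-exon
#'   `mu`, `sigma`, `n`, `k`, plus the thresholds used.
#' @export
copa_z <- function(matrix, trim_fraction = 0.75, z_min = 4, eps = 1e-8) {
  stopifnot(inherits(matrix, "ExonExpressionMatrix"),
            trim_fraction > 0, trim_fraction <= 1)
  x <- matrix$rpkm
  n <- ncol(x)
  if (n < 4L) stop("insufficient samples: COPA needs n >= 4, got ", n)
  k <- as.integer(ceiling(trim_fraction * n))
  mu <- numeric(nrow(x))
  sigma <- numeric(nrow(x))
  z <- x * 0
  for (i in seq_len(nrow(x))) {
    v <- sort(x[i, ])[seq_len(k)]
    mu[i] <- mean(v)
    sigma[i] <- if (k > 1L) sd(v) else 0
    z[i, ] <- if (sigma[i] < eps) 0 else (x[i, ] - mu[i]) / sigma[i]
  }
  structure(list(z = z, outlier = z > z_min, mu = mu, sigma = sigma,
                 n = n, k = k, z_min = z_min, eps = eps,
                 exons = matrix$exons),
            class = "CopaResult")
}

#' Select (gene, sample) pairs with outlier exon expression
#'
#' A gene/sample pair is selected when the gene has at least one exon whose
#' maximum RPKM across samples is strictly greater than `rpkm_min` and that
#' exon is a COPA outlier in that sample.
#'
#' @param copa A `CopaResult`.
#' @param matrix The `ExonExpressionMatrix` the result was computed on.
#' @param rpkm_min Expression floor (strict >; default 20).
#' @return data.frame with columns `gene_id`, `sample`.
#' @export
select_candidate_genes <- function(copa, matrix, rpkm_min = 20) {
  stopifnot(inherits(copa, "CopaResult"), inherits(matrix, "ExonExpressionMatrix"))
  eligible <- apply(matrix$rpkm, 1, max) > rpkm_min
  hits <- which(copa$outlier & eligible, arr.ind = TRUE)
  if (!nrow(hits)) {
    return(data.frame(gene_id = character(0), sample = character(0)))
  }
  out <- unique(data.frame(
    gene_id = matrix$exons$gene_id[hits[, 1]],
    sample = matrix$samples[hits[, 2]],
    stringsAsFactors = FALSE))
  out <- out[order(out$gene_id, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalized exon-walk profile for one gene and sample
#'
#' Each exon's RPKM is normalized by that exon's 70th-percentile RPKM across
#' samples (linear-interpolation percentile). Exons whose percentile
#' denominator is zero cohort-wide borrow the smallest positive denominator
#' of the gene; a gene with no positive denominator is skipped (NULL).
#'
#' @param matrix An `ExonExpressionMatrix`.
#' @param gene_id Gene identifier.
#' @param sample Sample identifier.
#' @param quantile Percentile for the denominator, 0 < q < 1 (default 0.70).
#' @return data.frame with `rank`, `rpkm`, `q`, `norm`; or NULL.
#' @export
walk_profile <- function(matrix, gene_id, sample, quantile = 0.70) {
  idx <- which(matrix$exons$gene_id == gene_id)
  if (!length(idx)) stop("gene '", gene_id, "' not in matrix")
  idx <- idx[order(matrix$exons$rank[idx])]
  q <- apply(matrix$rpkm[idx, , drop = FALSE], 1, stats::quantile,
             probs = quantile, names = FALSE)
  if (all(q <= 0)) return(NULL)
  q[q <= 0] <- min(q[q > 0])
  data.frame(rank = matrix$exons$rank[idx],
             rpkm = matrix$rpkm[idx, sample],
             q = q,
             norm = matrix$rpkm[idx, sample] / q)
}

#' Exon-walking breakpoint detection
#'
#' Walking the gene's exons 5' to 3' in transcript rank order, every adjacent
#' pair whose normalized RPKM changes by at least `fold` (drop:
#' `r[j+1] <= r[j]/fold`; rise: `r[j+1] >= fold * r[j]`) marks the exon-exon
#' boundary as a potential fusion breakpoint. A gene with at least one
#' candidate shows the 5'/3' expression imbalance that flags it for fusion
#' evaluation.
#'
#' @param matrix An `ExonExpressionMatrix`.
#' @param gene A `GeneModel` (or gene id present in the matrix).
#' @param sample Sample identifier.
#' @param fold Fold-change threshold (inclusive; default 2).
#' @param quantile Normalization percentile (default 0.70).
#' @return data.frame of `BreakpointCandidate` rows: `gene_id`, `sample`,
#'   `rank5`, `rank3` (the flanking transcript ranks), `direction`
#'   (`"drop"`/`"rise"`), `fold_change`. Empty for single-exon genes.
#' @export
walk_breakpoints <- function(matrix, gene, sample, fold = 2, quantile = 0.70) {
  gene_id <- if (is.character(gene)) gene else gene$gene_id
  empty <- data.frame(gene_id = character(0), sample = character(0),
                      rank5 = integer(0), rank3 = integer(0),
                      direction = character(0), fold_change = numeric(0))
  prof <- walk_profile(matrix, gene_id, sample, quantile)
  if (is.null(prof) || nrow(prof) < 2L) return(empty)
  r <- prof$norm
  out <- empty
  for (j in seq_len(nrow(prof) - 1L)) {
    a <- r[j]; b <- r[j + 1L]
    drop <- a > 0 && b <= a / fold
    rise <- b > 0 && b >= fold * a
    if (!drop && !rise) next
    fc <- if (drop) {
      if (b > 0) a / b else Inf
    } else {
      if (a > 0) b / a else Inf
    }
    out <- rbind(out, data.frame(
      gene_id = gene_id, sample = sample,
      rank5 = prof$rank[j], rank3 = prof$rank[j + 1L],
      direction = if (drop) "drop" else "rise",
      fold_change = fc, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
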