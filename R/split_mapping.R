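# ---------------------------------------------------------------------------
# Seed-and-extend split alignment of consensus sequences: one part anchored
# to the known exon flank, the remainder mapped genome-wide with exact
# 16-mer seeds and ungapped extension (match +1, mismatch -2). A distal
# locus is accepted only when its score beats the runner-up by min_margin.
# ---------------------------------------------------------------------------

.SCORE_MATCH <- 1
.SCORE_MISMATCH <- -2

.ungapped_score <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(va), length(vb))
  m <- sum(va[seq_len(n)] == vb[seq_len(n)])
  m * .SCORE_MATCH + (n - m) * .SCORE_MISMATCH
}

.identity_frac <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(va), length(vb))
  if (n == 0L) return(0)
  sum(va[seq_len(n)] == vb[seq_len(n)]) / n
}

# All ungapped alignments of `query` in the genome found by exact k-mer
# seeding at every query offset, extended across the full query. Returns a
# data.frame: chrom, strand, start0 (0-based genomic start of the full query
# alignment), score, identity.
.map_remainder <- function(query, genome, k = 16L) {
  qlen <- nchar(query)
  if (qlen < k) return(NULL)
  hits <- list()
  add_hits <- function(strand, q) {
    for (chrom in genome$chrom_names) {
      subj <- genome$sequences[[chrom]]
      for (off in seq.int(1L, qlen - k + 1L)) {
        seed <- substr(q, off, off + k - 1L)
        m <- matchPattern(seed, DNAString(subj))
        for (s in start(m)) {
          gstart0 <- s - 1L - (off - 1L)  # 0-based start of full query
          if (gstart0 < 0L || gstart0 + qlen > nchar(subj)) next
          key <- paste(chrom, strand, gstart0)
          if (!is.null(hits[[key]])) next
          ref <- substr(subj, gstart0 + 1L, gstart0 + qlen)
          hits[[key]] <<- data.frame(
            chrom = chrom, strand = strand, start0 = gstart0,
            score = .ungapped_score(q, ref),
            identity = .identity_frac(q, ref))
        }
      }
    }
  }
  add_hits("+", query)
  add_hits("-", revcomp(query))
  if (!length(hits)) return(NULL)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(-out$score, out$chrom, out$start0, out$strand), , drop = FALSE]
}

#' Split-align a consensus sequence and emit a fusion candidate
#'
#' The exon-side part of the consensus (up to its junction column) must match
#' the anchor gene's exon flank with identity at least 0.95; the remainder is
#' mapped genome-wide by exact 16-mer seeding and ungapped extension. A
#' candidate is emitted only when the best distal locus is unique (score
#' margin over the runner-up at least `min_margin`), lies outside the anchor
#' gene, and both parts are at least `min_part_len` long. Breakpoints are
#' 1-based: the last exon-side base (5' side) and the first distal base.
#'
#' @param consensus A `ConsensusSeq` (its `junction_col` separates exon part
#'   from tail).
#' @param genome A `GenomeRef`.
#' @param annotation An `AnnotationSet`.
#' @param anchor_gene The `GeneModel` whose exon flank anchors the consensus.
#' @param boundary 1-based genomic coordinate of the anchor exon boundary.
#' @param sample Sample id carried into the candidate.
#' @param min_part_len Minimum length of each part (default 20).
#' @param min_margin Required best-minus-second score margin (default 8).
#' @param min_exon_identity Identity floor for the exon-side part.
#' @return A `FusionCandidate` data.frame row, or a `NoCandidate` sentinel
#'   (empty list) whose `reason` attribute is one of `"no_split"`,
#'   `"low_exon_identity"`, `"non_unique"`, `"intragenic"`, `"no_hit"`.
#' @export
split_align <- function(consensus, genome, annotation, anchor_gene, boundary,
                        sample = NA_character_, min_part_len = 20L,
                        min_margin = 8, min_exon_identity = 0.95) {
  seq <- consensus$seq
  jc <- consensus$junction_col
  fail <- function(reason) structure(list(), class = "NoCandidate",
                                     reason = reason)
  if (jc < min_part_len || nchar(seq) - jc < min_part_len) {
    return(fail("no_split"))
  }
  exon_part <- substr(seq, 1L, jc)
  tail_part <- substring(seq, jc + 1L)

  # exon flank: the anchor exon sequence ending at `boundary` in transcript
  # orientation (strand-aware)
  strand5 <- anchor_gene$strand
  flank <- if (strand5 == "+") {
    genome_seq(genome, anchor_gene$chrom, boundary - jc, boundary, "+")
  } else {
    genome_seq(genome, anchor_gene$chrom, boundary - 1L, boundary - 1L + jc, "-")
  }
  if (.identity_frac(exon_part, flank) < min_exon_identity) {
    return(fail("low_exon_identity"))
  }

  hits <- .map_remainder(tail_part, genome)
  if (is.null(hits) || !nrow(hits)) return(fail("no_hit"))
  best <- hits[1, ]
  margin <- if (nrow(hits) >= 2L) best$score - hits$score[2] else Inf
  if (margin < min_margin) return(fail("non_unique"))

  span <- gene_span(anchor_gene)
  if (best$chrom == anchor_gene$chrom &&
      best$start0 < span[2] && (best$start0 + nchar(tail_part)) > span[1]) {
    return(fail("intragenic"))
  }

  # first distal base in fusion-transcript orientation, 1-based
  pos3 <- if (best$strand == "+") best$start0 + 1L else best$start0 + nchar(tail_part)
  partner <- classify_three_prime_partner(
    list(chrom = best$chrom, pos = pos3), annotation)
  gene3 <- if (partner == "UAR") "UAR" else {
    ids <- genes_at(annotation, best$chrom, pos3)
    annotation$genes[[ids[1]]]$symbol
  }
  data.frame(
    sample = sample,
    gene5 = anchor_gene$symbol, chrom5 = anchor_gene$chrom,
    strand5 = strand5, pos5 = boundary,
    gene3 = gene3, chrom3 = best$chrom, strand3 = best$strand, pos3 = pos3,
    partner_class = partner,
    junction_reads = length(consensus$members),
    identity3 = best$identity, margin = margin,
    fusion_seq = seq, source = "internal",
    stringsAsFactors = FALSE)
}

#' Classify the 3' partner locus of a fusion
#'
#' `annotated_coding` when the locus overlaps a coding gene model,
#' `annotated_noncoding` when only noncoding models overlap, and `"UAR"`
#' (unannotated region) when no model overlaps.
#'
#' @param locus list with `chrom`, `pos` (1-based).
#' @param annotation An `AnnotationSet`.
#' @return One of `"annotated_coding"`, `"annotated_noncoding"`, `"UAR"`.
#' @export
classify_three_prime_partner <- function(locus, annotation) {
  ids <- genes_at(annotation, locus$chrom, locus$pos)
  if (!length(ids)) return("UAR")
  bt <- vapply(ids, function(id) annotation$genes[[id]]$biotype, character(1))
  if (any(bt == "coding")) "annotated_coding" else "annotated_noncoding"
}

#' Count junction-spanning and wild-type-spanning reads
#'
#' A read supports a junction when it matches the junction's sequence window
#' exactly and covers the junction point with at least `min_anchor` bases on
#' each side. Wild-type counts are `NA` when no wild-type window is supplied
#' (an unannotated 3' partner has no wild-type junction).
#'
#' @param reads Character vector of base-space read sequences.
#' @param fusion_window Sequence window around the fusion junction.
#' @param fusion_junction 1-based offset in `fusion_window` of the last 5'
#'   base.
#' @param wt5_window,wt5_junction,wt3_window,wt3_junction The corresponding
#'   wild-type exon-exon junction windows (NULL/NA to skip).
#' @param min_anchor Minimum bases required on each side (default 10).
#' @return list `junction_reads`, `wt5`, `wt3`.
#' @export
count_junction_support <- function(reads, fusion_window, fusion_junction,
                                   wt5_window = NULL, wt5_junction = NA,
                                   wt3_window = NULL, wt3_junction = NA,
                                   min_anchor = 10L) {
  count_one <- function(window, junction) {
    if (is.null(window) || is.na(junction)) return(NA_integer_)
    n <- 0L
    for (r in reads) {
      at <- regexpr(r, window, fixed = TRUE)[1]
      if (at < 0) next
      left <- junction - at + 1L
      right <- nchar(r) - left
      if (left >= min_anchor && right >= min_anchor) n <- n + 1L
    }
    n
  }
  list(junction_reads = count_one(fusion_window, fusion_junction),
       wt5 = count_one(wt5_window, wt5_junction),
       wt3 = count_one(wt3_window, wt3_junction))
}
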