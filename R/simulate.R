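# ---------------------------------------------------------------------------
# Deterministic synthetic-cohort simulator: toy genomes, gene models,
# planted fusions (mechanism x structure class), color-space reads,
# expression matrices, copy-number segments and emulated caller files.
# Every artifact is a pure function of (config, seed).
# ---------------------------------------------------------------------------

#' Simulator configuration
#'
#' Defaults emulate the study conditions of a small single-end 50 bp
#' color-space cohort: 24 tumour samples, one planted fusion per affected
#' sample, junction depth 30x, 8-fold outlier overexpression of the fused
#' alleles, and log-normal background expression noise (sigma_log = 0.2).
#'
#' @param seed Integer seed; fixes every downstream artifact.
#' @param n_chromosomes Number of toy chromosomes (default 3).
#' @param chrom_length Bases per chromosome (default 4e5). Each chromosome
#'   carries an annotation-free tail region (>= 20 kb) acting as UAR
#'   substrate.
#' @param n_genes Total gene models (default 24; 3 noncoding per
#'   chromosome).
#' @param n_samples Cohort size (default 24).
#' @param fusion_specs data.frame with columns `mechanism`,
#'   `structure_class`, `expr_fold`, `depth`; default plants all eight
#'   structure classes paired with all six mechanisms (see
#'   [default_fusion_specs()]).
#' @param read_length Read length in bases (default 50).
#' @param error_rate Per-color error probability (default 0).
#' @param wt_depth Mean wild-type junction coverage (default 3).
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 3L, chrom_length = 400000L,
                       n_genes = 24L, n_samples = 24L,
                       fusion_specs = default_fusion_specs(),
                       read_length = 50L, error_rate = 0, wt_depth = 3) {
  stopifnot(seed == as.integer(seed), n_chromosomes >= 1L, n_samples >= 4L)
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length, n_genes = n_genes,
                 n_samples = n_samples, fusion_specs = fusion_specs,
                 read_length = read_length, error_rate = error_rate,
                 wt_depth = wt_depth),
            class = "SimConfig")
}

#' Default planted-fusion specification
#'
#' Eight fusions covering the eight chimeric structure classes and all six
#' copy-number mechanisms (complex and deletion occur twice).
#' @export
default_fusion_specs <- function() {
  data.frame(
    mechanism = c("focal_amplification", "complex", "tandem_duplication",
                  "interchromosomal", "deletion_based", "none",
                  "deletion_based", "complex"),
    structure_class = c("in_frame", "out_of_frame", "promoter_swap_full",
                        "promoter_swap_n_truncated", "noncoding_truncation",
                        "truncated_gene", "extended_3utr", "no_protein"),
    expr_fold = 8,
    depth = 30,
    stringsAsFactors = FALSE)
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.codon_pool <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c(.STOP_CODONS, "ATG"))
})

# Random CDS: ATG + non-stop codons + TAA, length `len` (multiple of 3)
.random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  paste0("ATG", paste(sample(.codon_pool, len / 3 - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

#' Simulate a toy genome and annotation
#'
#' Chromosomes are uniform-random sequence. Genes are packed left to right
#' from 50 kb with 15-25 kb intergenic gaps, leaving an annotation-free
#' region of at least 20 kb at the right end of each chromosome (the UAR
#' substrate). Coding genes have 4-9 exons; the CDS starts in exon 2 and
#' ends inside the second-to-last exon (so both promoter-only and
#' 3'-UTR-only junctions exist at exon boundaries), is free of premature
#' stops, and is written into the genome. Three genes per chromosome are
#' noncoding. Reproducible per seed.
#'
#' @param config A `SimConfig`.
#' @return list with `genome` (a `GenomeRef`), `annotation` (an
#'   `AnnotationSet`), and `uar_regions` (per-chromosome 1-based intervals
#'   free of annotation).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  L <- config$chrom_length
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  seqs <- lapply(chroms, function(ch) {
    strsplit(.random_bases(L), "", fixed = TRUE)[[1]]
  })
  names(seqs) <- chroms

  per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  models <- list()
  gi <- 0L
  uar_regions <- list()
  for (ci in seq_along(chroms)) {
    pos <- 50000L
    n_here <- min(per_chrom, config$n_genes - (ci - 1L) * per_chrom)
    if (n_here <= 0L) break
    noncoding_here <- utils::tail(seq_len(n_here), 3L)
    for (k in seq_len(n_here)) {
      gi <- gi + 1L
      n_ex <- sample(4:9, 1)
      ex_len <- sample(150:240, n_ex, replace = TRUE)
      in_len <- sample(300:800, n_ex - 1, replace = TRUE)
      strand <- sample(c("+", "-"), 1)
      gspan <- sum(ex_len) + sum(in_len)
      if (pos + gspan > L - 100000L) {
        stop("genes requested exceed packing capacity on ", chroms[ci])
      }
      # genomic exon layout, left to right
      gstart <- pos
      starts <- integer(n_ex)
      ends <- integer(n_ex)
      p <- gstart
      for (e in seq_len(n_ex)) {
        starts[e] <- p
        ends[e] <- p + ex_len[e]
        p <- ends[e] + if (e < n_ex) in_len[e] else 0L
      }
      # transcript orientation
      if (strand == "+") {
        exons <- data.frame(start = starts, end = ends)
        tx_lens <- ex_len
      } else {
        exons <- data.frame(start = rev(starts), end = rev(ends))
        tx_lens <- rev(ex_len)
      }
      tlen <- sum(tx_lens)
      coding <- !(k %in% noncoding_here)
      cds_span <- NULL
      tx <- .random_bases(tlen)
      if (coding) {
        cum <- cumsum(tx_lens)
        utr5 <- tx_lens[1] + sample(15:45, 1)
        cds_end_max <- cum[n_ex - 1L] - sample(10:40, 1)
        cds_len <- cds_end_max - utr5
        cds_len <- cds_len - (cds_len %% 3L)
        if (cds_len < 150L) stop("gene too short for CDS; widen exon sizes")
        cds_span <- c(utr5 + 1L, utr5 + cds_len)
        tx <- paste0(substr(tx, 1L, utr5), .random_cds(cds_len),
                     substring(tx, utr5 + cds_len + 1L))
      }
      id <- sprintf("G%03d", gi)
      m <- gene_model(gene_id = id, symbol = id, chrom = chroms[ci],
                      strand = strand, exons = exons, cds_span = cds_span,
                      biotype = if (coding) "coding" else "noncoding",
                      sources = "sim")
      models[[length(models) + 1L]] <- m
      # write the transcript into the chromosome
      tx_vec <- strsplit(tx, "", fixed = TRUE)[[1]]
      off <- 0L
      for (e in seq_len(n_ex)) {
        piece <- tx_vec[(off + 1L):(off + tx_lens[e])]
        s0 <- m$exons$start[e]
        e0 <- m$exons$end[e]
        if (strand == "-") {
          piece <- rev(chartr("ACGT", "TGCA", piece))
        }
        seqs[[chroms[ci]]][(s0 + 1L):e0] <- piece
        off <- off + tx_lens[e]
      }
      pos <- p + sample(15000:25000, 1)
    }
    uar_regions[[chroms[ci]]] <- c(pos + 20000L, L - 20000L)
  }
  genome <- genome_ref(lapply(seqs, paste, collapse = ""))
  list(genome = genome, annotation = annotation_set(models),
       uar_regions = uar_regions)
}

# transcript-oriented genomic coordinate (1-based) of the last base of exon
# `rank` of a model, and of the first base
.exon_last_gpos <- function(m, rank) {
  if (m$strand == "+") m$exons$end[rank] else m$exons$start[rank] + 1L
}
.exon_first_gpos <- function(m, rank) {
  if (m$strand == "+") m$exons$start[rank] + 1L else m$exons$end[rank]
}

.tx_cum <- function(m) cumsum(m$exons$end - m$exons$start)

# search exon-boundary pairs of two coding models for a junction with the
# requested frame relation; returns list(r, s) or NULL
.find_frame_pair <- function(m5, m3, genome, in_frame) {
  cum5 <- .tx_cum(m5); cum3 <- .tx_cum(m3)
  tx5 <- transcript_seq(m5, genome); tx3 <- transcript_seq(m3, genome)
  n5 <- nrow(m5$exons); n3 <- nrow(m3$exons)
  for (r in 2:(n5 - 2L)) {
    jc <- cum5[r]
    if (jc < m5$cds_span[1] || jc >= m5$cds_span[2]) next
    c5 <- jc - m5$cds_span[1] + 1L
    for (s in 3:(n3 - 1L)) {
      entry <- cum3[s - 1L] + 1L
      into <- entry - m3$cds_span[1]
      if (into <= 0 || entry >= m3$cds_span[2]) next
      phase_ok <- (c5 %% 3L) == (into %% 3L)
      if (phase_ok != in_frame) next
      if (in_frame) {
        # reject junctions whose hybrid codon creates a premature stop
        fused <- paste0(substr(tx5, 1, jc), substring(tx3, entry))
        pep <- .translate_from(fused, m5$cds_span[1])
        want <- (jc - m5$cds_span[1] + 1L) %/% 3L
        if (nchar(pep) <= want) next
      }
      return(list(r = r, s = s))
    }
  }
  NULL
}

# copy-number segment rows embodying one mechanism around fusion points
# p5/p3 (1-based) on chromosome(s); means in log2 units
.mechanism_segments <- function(mechanism, sample, chrom5, p5, chrom3, p3, L) {
  seg <- function(chrom, start, end, mean) {
    data.frame(sample = sample, chrom = chrom, start = start, end = end,
               n_markers = NA_integer_, seg_mean = mean)
  }
  flat <- function(chrom) seg(chrom, 1L, L, 0)
  if (mechanism == "interchromosomal") {
    return(rbind(seg(chrom5, 1L, p5, 0.8), seg(chrom5, p5 + 1L, L, 0),
                 flat(chrom3)))
  }
  lo <- min(p5, p3); hi <- max(p5, p3)
  switch(mechanism,
    none = flat(chrom5),
    focal_amplification = rbind(
      seg(chrom5, 1L, lo - 45000L, 0),
      seg(chrom5, lo - 44999L, hi + 45000L, 2.0),
      seg(chrom5, hi + 45001L, L, 0)),
    tandem_duplication = rbind(
      # amplified segment runs from the 3' point to the 5' point
      seg(chrom5, 1L, p3 - 1L, 0),
      seg(chrom5, p3, p5, 1.8),
      seg(chrom5, p5 + 1L, L, 0)),
    deletion_based = rbind(
      seg(chrom5, 1L, lo - 1L, 0.5),
      seg(chrom5, lo, hi, -0.8),
      seg(chrom5, hi + 1L, L, 0.5)),
    complex = {
      q1 <- lo + 30000L
      q3 <- hi - 30001L
      q2 <- q1 + floor((q3 - q1) / 2)
      if (!(q1 < q2 && q2 < q3)) {
        stop("partners too close for a complex profile: ", hi - lo, " bp")
      }
      rbind(seg(chrom5, 1L, lo - 1L, 0),
            seg(chrom5, lo, q1, 1.5),
            seg(chrom5, q1 + 1L, q2, -0.5),
            seg(chrom5, q2 + 1L, q3, 1.2),
            seg(chrom5, q3 + 1L, hi, -0.3),
            seg(chrom5, hi + 1L, L, 0))
    },
    stop("unknown mechanism '", mechanism, "'"))
}

#' Plant fusions into a simulated reference
#'
#' For each fusion spec, chooses compatible partner loci, realizes the
#' requested structure class by junction placement and partner biotype,
#' builds the fused transcript, and constructs a per-sample copy-number
#' segment profile embodying the requested mechanism (e.g. a tandem
#' duplication is one amplified segment whose endpoints coincide with the
#' fusion points; a complex rearrangement has multiple alternating segments
#' between matched breakpoints). Each fusion occupies its own sample.
#'
#' @param config A `SimConfig`.
#' @param reference Output of [simulate_reference()].
#' @return list with `truth` (data.frame of `TruthRecord` rows), `segsets`
#'   (named list of `SegmentSet`, one per sample), and `fused_seqs` (named
#'   list of fused transcripts, the rearranged haplotype sequences).
#' @export
plant_fusions <- function(config, reference) {
  set.seed(config$seed + 1L)
  ann <- reference$annotation
  genome <- reference$genome
  specs <- config$fusion_specs
  L <- config$chrom_length
  if (any(specs$mechanism == "interchromosomal") && config$n_chromosomes < 2L) {
    stop("impossible spec: interchromosomal fusion on a 1-chromosome genome")
  }
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  if (nrow(specs) > config$n_samples) stop("more fusions than samples")

  by_chrom <- split(names(ann$genes),
                    vapply(ann$genes, `[[`, character(1), "chrom"))
  used <- character(0)
  # first free gene on `chrom` meeting the constraints, or NULL
  pick_on <- function(chrom, biotype, exclude = character(0), min_exons = 4L,
                      pred = function(m) TRUE) {
    pool <- setdiff(by_chrom[[chrom]], c(used, exclude))
    pool <- Filter(function(id) {
      m <- ann$genes[[id]]
      m$biotype == biotype && nrow(m$exons) >= min_exons && pred(m)
    }, pool)
    if (!length(pool)) NULL else pool[[1]]
  }
  # same, trying a preferred chromosome first and falling back to the rest
  pick_any <- function(pref, biotype, exclude = character(0), min_exons = 4L,
                       pred = function(m) TRUE) {
    for (ch in unique(c(pref, names(by_chrom)))) {
      id <- pick_on(ch, biotype, exclude, min_exons, pred)
      if (!is.null(id)) return(ann$genes[[id]])
    }
    stop("no available ", biotype, " gene for the requested fusion layout")
  }
  # curation discards fusions of immediate neighbors, so planted partners
  # must never be adjacent genes
  not_adj <- function(other) function(m) !are_adjacent_genes(m, other, ann)
  chroms <- names(by_chrom)

  truth <- list()
  fused_seqs <- list()
  seg_rows <- list()
  for (i in seq_len(nrow(specs))) {
    mech <- specs$mechanism[i]
    sclass <- specs$structure_class[i]
    sample <- samples[i]
    chromA <- chroms[(i - 1L) %% length(chroms) + 1L]
    chromB <- if (mech == "interchromosomal") {
      chroms[i %% length(chroms) + 1L]
    } else chromA

    g5 <- NULL; g3 <- NULL; r <- NULL; s <- NULL
    pref <- unique(c(chromA, chroms))
    # partner-chromosome pool for a given 5' chromosome
    partner_chroms <- function(ch5) {
      if (mech == "interchromosomal") setdiff(chroms, ch5) else ch5
    }
    # a 5' gene whose UAR point keeps the required segment geometry inside
    # the chromosome
    uar_ok <- function(m) {
      u <- reference$uar_regions[[m$chrom]]
      p5max <- gene_span(m)[2]
      if (mech == "complex") {
        max(u[1], p5max + 70000L) + 9999L <= L - 31000L
      } else {
        u[1] + 19999L <= L - 31000L
      }
    }

    if (sclass %in% c("in_frame", "out_of_frame")) {
      # search coding pairs for a frame-compatible junction, preferred
      # chromosome first
      found <- FALSE
      for (ch5 in pref) {
        pool5 <- setdiff(by_chrom[[ch5]], used)
        pool3 <- setdiff(unlist(by_chrom[partner_chroms(ch5)]), used)
        for (id5 in pool5) {
          m5 <- ann$genes[[id5]]
          if (m5$biotype != "coding" || nrow(m5$exons) < 4L) next
          for (id3 in setdiff(pool3, id5)) {
            m3 <- ann$genes[[id3]]
            if (m3$biotype != "coding" || nrow(m3$exons) < 4L) next
            if (mech == "complex") {
              # complex profiles need well-separated partners
              d <- abs(.exon_last_gpos(m5, 2L) - .exon_first_gpos(m3, 2L))
              if (d < 80000L) next
            }
            if (m5$chrom == m3$chrom && are_adjacent_genes(m5, m3, ann)) next
            hit <- .find_frame_pair(m5, m3, genome, sclass == "in_frame")
            if (!is.null(hit)) {
              g5 <- m5; g3 <- m3; r <- hit$r; s <- hit$s; found <- TRUE; break
            }
          }
          if (found) break
        }
        if (found) break
      }
      if (!found) stop("no frame-compatible gene pair for ", sclass)
    } else if (sclass == "promoter_swap_full") {
      if (mech == "tandem_duplication") {
        # duplication geometry: 3' partner upstream of the 5' point, so pick
        # the upstream (first-placed) gene as the 3' partner and a
        # non-adjacent downstream gene as the 5' partner
        for (ch in pref) {
          id3 <- pick_on(ch, "coding")
          if (is.null(id3)) next
          g3_try <- ann$genes[[id3]]
          id5 <- pick_on(ch, "coding", exclude = id3,
                         pred = function(m) {
                           !are_adjacent_genes(m, g3_try, ann) &&
                             gene_span(m)[1] > gene_span(g3_try)[2]
                         })
          if (!is.null(id5)) {
            g3 <- g3_try; g5 <- ann$genes[[id5]]; break
          }
        }
        if (is.null(g5)) stop("no gene pair for a tandem-duplication layout")
      } else {
        g5 <- pick_any(pref, "coding")
        g3 <- pick_any(partner_chroms(g5$chrom), "coding",
                       exclude = g5$gene_id,
                       pred = if (mech == "interchromosomal") function(m) TRUE
                              else not_adj(g5))
      }
      r <- 1L; s <- 1L
    } else if (sclass == "promoter_swap_n_truncated") {
      g5 <- pick_any(pref, "coding")
      g3 <- pick_any(partner_chroms(g5$chrom), "coding", exclude = g5$gene_id,
                     pred = if (mech == "interchromosomal") function(m) TRUE
                            else not_adj(g5))
      r <- 1L; s <- 3L
    } else if (sclass == "noncoding_truncation") {
      g5 <- pick_any(pref, "coding", min_exons = 5L)
      g3 <- pick_any(partner_chroms(g5$chrom), "noncoding",
                     exclude = g5$gene_id,
                     pred = if (mech == "interchromosomal") function(m) TRUE
                            else not_adj(g5))
      r <- 3L; s <- 2L
    } else if (sclass == "truncated_gene") {
      g5 <- pick_any(pref, "coding", min_exons = 5L, pred = uar_ok)
      r <- 3L
    } else if (sclass == "extended_3utr") {
      g5 <- pick_any(pref, "coding", pred = uar_ok)
      r <- nrow(g5$exons) - 1L  # boundary after the CDS end
    } else if (sclass == "no_protein") {
      g5 <- pick_any(pref, "noncoding", pred = uar_ok)
      r <- 2L
    } else {
      stop("unknown structure class '", sclass, "'")
    }
    chromA <- g5$chrom
    uarA <- reference$uar_regions[[chromA]]

    p5 <- .exon_last_gpos(g5, r)
    jc_tx <- .tx_cum(g5)[r]
    tx5 <- transcript_seq(g5, genome)
    seq5 <- substr(tx5, 1L, jc_tx)

    if (is.null(g3)) {
      # UAR partner on an annotation-free chromosome tail; complex profiles
      # need the two fusion points well separated
      chrom3 <- if (mech == "interchromosomal") {
        setdiff(chroms, chromA)[1]
      } else chromA
      uar3 <- reference$uar_regions[[chrom3]]
      p3 <- if (mech == "complex") {
        as.integer(max(uar3[1], p5 + 70000L) + sample(0:9999, 1))
      } else {
        as.integer(uar3[1] + sample(0:19999, 1))
      }
      if (p3 > L - 31000L) stop("UAR point too close to the chromosome end")
      strand3 <- "+"
      seq3 <- genome_seq(genome, chrom3, p3 - 1L,
                         min(chrom_length(genome, chrom3), p3 - 1L + 10000L),
                         "+")
      gene3_sym <- "UAR"
    } else {
      p3 <- .exon_first_gpos(g3, s)
      chrom3 <- g3$chrom
      strand3 <- g3$strand
      entry_tx <- if (s == 1L) 1L else .tx_cum(g3)[s - 1L] + 1L
      seq3 <- substring(transcript_seq(g3, genome), entry_tx)
      gene3_sym <- g3$symbol
    }

    if (mech == "tandem_duplication" && p3 >= p5) {
      # duplication geometry needs the 3' point upstream of the 5' point;
      # swap in an upstream partner by retrying with reversed roles
      stop("tandem duplication spec needs a 3' partner upstream of the 5' ",
           "point; adjust gene packing or spec order")
    }

    used <- c(used, g5$gene_id, if (!is.null(g3)) g3$gene_id)
    fused <- paste0(seq5, seq3)
    fid <- sprintf("F%02d", i)
    fused_seqs[[fid]] <- fused
    truth[[i]] <- data.frame(
      fusion_id = fid, sample = sample,
      gene5 = g5$symbol, gene5_id = g5$gene_id, chrom5 = g5$chrom,
      strand5 = g5$strand, pos5 = p5, rank5 = r,
      gene3 = gene3_sym, gene3_id = if (is.null(g3)) NA_character_ else g3$gene_id,
      chrom3 = chrom3, strand3 = strand3, pos3 = p3,
      rank3 = if (is.null(g3)) NA_integer_ else s,
      mechanism = mech, structure_class = sclass,
      expr_fold = specs$expr_fold[i], depth = specs$depth[i],
      junction_tx = jc_tx,
      stringsAsFactors = FALSE)
    seg_rows[[sample]] <- .mechanism_segments(mech, sample, g5$chrom, p5,
                                              chrom3, p3, L)
  }
  truth <- do.call(rbind, truth)

  # complete every sample's profile: flat segments on untouched chromosomes
  segsets <- list()
  for (smp in samples) {
    rows <- seg_rows[[smp]]
    covered <- if (is.null(rows)) character(0) else unique(rows$chrom)
    flat <- do.call(rbind, lapply(setdiff(paste0("chr", seq_len(config$n_chromosomes)),
                                          covered), function(ch) {
      data.frame(sample = smp, chrom = ch, start = 1L, end = L,
                 n_markers = NA_integer_, seg_mean = 0)
    }))
    segsets[[smp]] <- segment_set(rbind(rows, flat))
  }
  list(truth = truth, segsets = segsets, fused_seqs = fused_seqs)
}

.mutate_colors <- function(colors, error_rate) {
  if (error_rate <= 0) return(colors)
  v <- as.integer(strsplit(colors, "", fixed = TRUE)[[1]])
  hit <- runif(length(v)) < error_rate
  if (any(hit)) {
    v[hit] <- (v[hit] + sample(1:3, sum(hit), replace = TRUE)) %% 4L
  }
  paste(v, collapse = "")
}

#' Simulate reads and the exon expression matrix for a planted cohort
#'
#' Background exon counts are log-normal (sigma_log = 0.2) around a common
#' baseline; in each fused sample the retained 5' exons (and retained 3'
#' partner exons, when annotated) are multiplied by the planted expression
#' fold, producing the outlier level and the 5'/3' walk imbalance. Junction
#' reads are drawn Poisson(depth) with uniform offsets chosen so the
#' exon-side anchor spans 12-30 bases (always below the 35-base partial-read
#' cutoff); wild-type junction reads at the corresponding exon-exon
#' junctions are drawn Poisson(`wt_depth`) and carry a full-length match.
#' Per-color errors are applied at the configured rate.
#'
#' @param config A `SimConfig`.
#' @param reference Output of [simulate_reference()].
#' @param planted Output of [plant_fusions()].
#' @return list with `matrix` (an `ExonExpressionMatrix`), `reads`
#'   (data.frame: sample, id, gene_id, boundary, kind, primer, colors,
#'   matched_length, bases), and `truth` (the planted truth with junction
#'   window columns added).
#' @export
simulate_reads_and_expression <- function(config, reference, planted) {
  set.seed(config$seed + 2L)
  ann <- reference$annotation
  genome <- reference$genome
  truth <- planted$truth
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  rl <- config$read_length

  exons <- .annotation_exon_table(ann)
  n_ex <- nrow(exons)
  base_mean <- 80
  counts <- matrix(rlnorm(n_ex * length(samples), meanlog = log(base_mean),
                          sdlog = 0.2),
                   nrow = n_ex, dimnames = list(NULL, samples))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    i5 <- which(exons$gene_id == tr$gene5_id & exons$rank <= tr$rank5)
    counts[i5, tr$sample] <- counts[i5, tr$sample] * tr$expr_fold
    if (!is.na(tr$gene3_id)) {
      i3 <- which(exons$gene_id == tr$gene3_id & exons$rank >= tr$rank3)
      counts[i3, tr$sample] <- counts[i3, tr$sample] * tr$expr_fold
    }
  }
  counts <- round(counts)
  mat <- exon_expression_matrix(exons, counts,
                                total_reads = rep(2e7, length(samples)))

  reads <- list()
  windows <- data.frame(fusion_id = truth$fusion_id,
                        fusion_window = NA_character_,
                        fusion_junction = NA_integer_,
                        wt5_window = NA_character_, wt5_junction = NA_integer_,
                        wt3_window = NA_character_, wt3_junction = NA_integer_,
                        stringsAsFactors = FALSE)
  add_junction_reads <- function(window, junction, n, prefix, sample,
                                 gene_id, boundary, kind) {
    if (n <= 0L) return(NULL)
    m <- sample(12:30, n, replace = TRUE)
    do.call(rbind, lapply(seq_len(n), function(j) {
      bases <- substr(window, junction - m[j] + 1L, junction - m[j] + rl)
      data.frame(sample = sample, id = paste0(prefix, "_", j),
                 gene_id = gene_id, boundary = boundary, kind = kind,
                 primer = "T",
                 colors = .mutate_colors(encode_colors("T", bases),
                                         config$error_rate),
                 matched_length = if (kind == "junction") m[j] else rl,
                 bases = bases, stringsAsFactors = FALSE)
    }))
  }

  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    fused <- planted$fused_seqs[[tr$fusion_id]]
    jc <- tr$junction_tx
    lo <- max(1L, jc - 60L)
    win <- substr(fused, lo, min(nchar(fused), jc + 60L))
    jwin <- jc - lo + 1L
    windows$fusion_window[i] <- win
    windows$fusion_junction[i] <- jwin
    n_j <- rpois(1, tr$depth)
    reads[[length(reads) + 1L]] <- add_junction_reads(
      win, jwin, n_j, paste0(tr$fusion_id, "_J"), tr$sample,
      tr$gene5_id, tr$pos5, "junction")

    # wild-type junction of the 5' gene at the same boundary
    m5 <- ann$genes[[tr$gene5_id]]
    if (tr$rank5 < nrow(m5$exons)) {
      tx5 <- transcript_seq(m5, genome)
      lo5 <- max(1L, jc - 60L)
      w5 <- substr(tx5, lo5, min(nchar(tx5), jc + 60L))
      j5 <- jc - lo5 + 1L
      windows$wt5_window[i] <- w5
      windows$wt5_junction[i] <- j5
      reads[[length(reads) + 1L]] <- add_junction_reads(
        w5, j5, rpois(1, config$wt_depth), paste0(tr$fusion_id, "_W5"),
        tr$sample, tr$gene5_id, tr$pos5, "wt5")
    }
    if (!is.na(tr$gene3_id)) {
      m3 <- ann$genes[[tr$gene3_id]]
      entry_tx <- if (tr$rank3 == 1L) 1L else .tx_cum(m3)[tr$rank3 - 1L] + 1L
      if (entry_tx > 1L) {
        tx3 <- transcript_seq(m3, genome)
        ej <- entry_tx - 1L  # last base of the upstream wild-type exon
        lo3 <- max(1L, ej - 60L)
        w3 <- substr(tx3, lo3, min(nchar(tx3), ej + 60L))
        j3 <- ej - lo3 + 1L
        windows$wt3_window[i] <- w3
        windows$wt3_junction[i] <- j3
        reads[[length(reads) + 1L]] <- add_junction_reads(
          w3, j3, rpois(1, config$wt_depth), paste0(tr$fusion_id, "_W3"),
          tr$sample, tr$gene3_id, tr$pos3, "wt3")
      }
    }
  }
  reads <- do.call(rbind, reads)
  rownames(reads) <- NULL
  list(matrix = mat, reads = reads, truth = cbind(truth, windows[, -1]))
}

#' Run the full simulator
#'
#' Convenience wrapper: reference, planted fusions, reads and expression in
#' one call.
#' @param config A `SimConfig`.
#' @return list with `reference`, `planted`, `data` (reads + matrix +
#'   truth).
#' @export
simulate_cohort <- function(config = sim_config()) {
  reference <- simulate_reference(config)
  planted <- plant_fusions(config, reference)
  data <- simulate_reads_and_expression(config, reference, planted)
  list(config = config, reference = reference, planted = planted, data = data)
}

# ---------------------------------------------------------------------------
# Emulated caller files
# ---------------------------------------------------------------------------

.orient_of <- function(strand) ifelse(strand == "+", "f", "r")

#' Render truth (plus rule-violating decoys) in a caller dialect
#'
#' Truth records satisfy every curation rule; each decoy violates exactly
#' one targeted rule (`boundary`, `ratio`, `support`, `candidate_only`,
#' `orientation`, `blacklist`, `adjacent`). A sidecar table labels every
#' record and carries its wild-type junction counts.
#'
#' @param truth Planted truth data.frame (from [plant_fusions()] or
#'   [simulate_reads_and_expression()]).
#' @param annotation The simulated `AnnotationSet`.
#' @param dir Output directory.
#' @param dialect `"tophatfusion"` (writes `potential_fusion.txt` and
#'   `result.txt`) or `"snowshoes"` (writes `final_fusion_report_RNA.txt`).
#' @param decoys Character vector of rule names to violate (possibly with
#'   repeats); default one decoy per rule.
#' @param seed Seed for decoy placement.
#' @param span_reads Spanning reads given to truth records (default 120).
#' @return list with `paths` (written files) and `sidecar` (the label
#'   table, also written to `truth_records.tsv`).
#' @export
emit_caller_files <- function(truth, annotation, dir,
                              dialect = c("tophatfusion", "snowshoes"),
                              decoys = c("boundary", "ratio", "support",
                                         "candidate_only", "orientation",
                                         "blacklist", "adjacent"),
                              seed = 1L, span_reads = 120) {
  dialect <- match.arg(dialect)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (dialect == "snowshoes") {
    # the candidate-only concept exists only for the two-file caller layout
    decoys <- setdiff(decoys, "candidate_only")
  }

  rec <- data.frame(
    sample = truth$sample, gene5 = truth$gene5, gene3 = truth$gene3,
    chrom5 = truth$chrom5, pos5 = truth$pos5,
    strand5 = truth$strand5,
    chrom3 = truth$chrom3, pos3 = truth$pos3, strand3 = truth$strand3,
    orient5 = .orient_of(truth$strand5), orient3 = .orient_of(truth$strand3),
    span_reads = span_reads, candidate_only = FALSE,
    label = "truth", violated = NA_character_,
    wt5 = 3, wt3 = ifelse(truth$gene3 == "UAR", NA, 3),
    stringsAsFactors = FALSE)

  # helper: a clean template record on real exon boundaries of two
  # non-adjacent genes not used by the truth set
  ids <- names(annotation$genes)
  free <- setdiff(ids, c(truth$gene5_id, truth$gene3_id))
  template <- function(offset = 0L) {
    g5 <- annotation$genes[[free[1 + offset]]]
    g3 <- annotation$genes[[free[3 + offset]]]  # one gene between -> not adjacent
    data.frame(
      sample = "S01", gene5 = g5$symbol, gene3 = g3$symbol,
      chrom5 = g5$chrom, pos5 = .exon_last_gpos(g5, 2L), strand5 = g5$strand,
      chrom3 = g3$chrom, pos3 = .exon_first_gpos(g3, 2L), strand3 = g3$strand,
      orient5 = .orient_of(g5$strand), orient3 = .orient_of(g3$strand),
      span_reads = 150, candidate_only = FALSE,
      label = "decoy", violated = NA_character_, wt5 = 0, wt3 = 0,
      stringsAsFactors = FALSE)
  }
  drows <- list()
  for (k in seq_along(decoys)) {
    d <- template(k %% max(1L, length(free) - 4L))
    d$violated <- decoys[k]
    if (decoys[k] == "boundary") {
      d$pos5 <- d$pos5 + 17L; d$pos3 <- d$pos3 + 17L
    } else if (decoys[k] == "ratio") {
      d$wt5 <- 80; d$wt3 <- 80
    } else if (decoys[k] == "support") {
      # unannotated symbols keep the partner outlier z undefined, so the
      # record can only pass on spanning reads (and does not)
      d$span_reads <- 20
      d$gene5 <- "DECOYS5"; d$gene3 <- "DECOYS3"
    } else if (decoys[k] == "candidate_only") {
      d$candidate_only <- TRUE
    } else if (decoys[k] == "orientation") {
      # flip both the orientation flag and the reported strand so the
      # violation survives dialects that only carry strand columns
      d$orient5 <- if (d$orient5 == "f") "r" else "f"
      d$strand5 <- if (d$strand5 == "+") "-" else "+"
    } else if (decoys[k] == "blacklist") {
      d$gene5 <- "TFG"; d$gene3 <- "GPR128"
    } else if (decoys[k] == "adjacent") {
      # immediate neighbors on the same chromosome
      ch <- d$chrom5
      here <- Filter(function(id) annotation$genes[[id]]$chrom == ch, ids)
      spans <- vapply(here, function(id) gene_span(annotation$genes[[id]])[1],
                      numeric(1))
      here <- here[order(spans)]
      a <- annotation$genes[[here[1]]]; b <- annotation$genes[[here[2]]]
      d$gene5 <- a$symbol; d$gene3 <- b$symbol
      d$chrom5 <- a$chrom; d$pos5 <- .exon_last_gpos(a, 2L); d$strand5 <- a$strand
      d$chrom3 <- b$chrom; d$pos3 <- .exon_first_gpos(b, 2L); d$strand3 <- b$strand
      d$orient5 <- .orient_of(a$strand); d$orient3 <- .orient_of(b$strand)
    } else {
      stop("unknown decoy rule '", decoys[k], "'")
    }
    drows[[k]] <- d
  }
  all <- rbind(rec, do.call(rbind, drows))
  all$record_id <- sprintf("R%03d", seq_len(nrow(all)))

  paths <- character(0)
  if (dialect == "tophatfusion") {
    pot <- file.path(dir, "potential_fusion.txt")
    res <- file.path(dir, "result.txt")
    writeLines(vapply(seq_len(nrow(all)), function(i) {
      r <- all[i, ]
      paste(r$sample, paste0(r$chrom5, "-", r$chrom3), r$pos5, r$pos3,
            paste0(r$orient5, r$orient3), r$span_reads, 0, sep = "\t")
    }, character(1)), pot)
    keep <- !all$candidate_only
    writeLines(vapply(which(keep), function(i) {
      r <- all[i, ]
      paste(r$sample, r$gene5, r$chrom5, r$pos5, r$gene3, r$chrom3, r$pos3,
            r$span_reads, 0, paste0(r$orient5, r$orient3), sep = "\t")
    }, character(1)), res)
    paths <- c(potential = pot, result = res)
  } else {
    ss <- file.path(dir, "final_fusion_report_RNA.txt")
    writeLines(vapply(seq_len(nrow(all)), function(i) {
      r <- all[i, ]
      paste(r$sample, r$gene5, r$chrom5, r$pos5, r$strand5,
            r$gene3, r$chrom3, r$pos3, r$strand3, r$span_reads, 1, sep = "\t")
    }, character(1)), ss)
    paths <- c(snowshoes = ss)
  }
  sidecar_path <- file.path(dir, "truth_records.tsv")
  write.table(all, sidecar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(paths = paths, sidecar = all, sidecar_path = sidecar_path)
}
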