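#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps granges
#'   seqnames strand start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
#'   readDNAStringSet writeXStringSet matchPattern translate
#' @importFrom utils read.delim write.table head tail
#' @importFrom stats quantile sd rpois rnorm rlnorm runif setNames aggregate cor
NULL

# ---------------------------------------------------------------------------
# Genome reference: a named list of uppercase nucleotide strings.
# Internal coordinates are 0-based half-open; everything printed or read from
# standard formats (GTF, SEG, report tables) is 1-based inclusive.
# ---------------------------------------------------------------------------

#' Construct a genome reference
#'
#' @param sequences Named character vector or list of nucleotide strings
#'   (uppercased on construction); names are chromosome identifiers.
#' @return An object of class `GenomeRef`.
#' @export
genome_ref <- function(sequences) {
  sequences <- as.list(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))) ||
      anyDuplicated(names(sequences))) {
    stop("sequences must have unique non-empty chromosome names")
  }
  sequences <- lapply(sequences, function(s) toupper(as.character(s)))
  if (any(!nzchar(unlist(sequences)))) stop("empty chromosome sequence")
  bad <- vapply(sequences, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) stop("non-ACGTN characters in chromosome(s): ",
                     paste(names(sequences)[bad], collapse = ", "))
  structure(list(chrom_names = names(sequences), sequences = sequences),
            class = "GenomeRef")
}

#' Length of a chromosome
#' @param genome A `GenomeRef`.
#' @param chrom Chromosome name.
#' @export
chrom_length <- function(genome, chrom) {
  s <- genome$sequences[[chrom]]
  if (is.null(s)) stop("unknown chromosome '", chrom, "'")
  nchar(s)
}

#' Extract genomic sequence
#'
#' @param genome A `GenomeRef`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`; minus returns the reverse complement.
#' @return Nucleotide string.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  s <- genome$sequences[[chrom]]
  if (is.null(s)) stop("unknown chromosome '", chrom, "'")
  if (start < 0 || end > nchar(s) || start >= end) {
    stop("interval [", start, ",", end, ") outside [0,", nchar(s), ") on ", chrom)
  }
  out <- substr(s, start + 1L, end)
  if (strand == "-") out <- revcomp(out)
  out
}

#' Reverse complement of a nucleotide string
#' @param x Nucleotide string.
#' @export
revcomp <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

#' Read a genome from FASTA
#' @param path FASTA path (gzip accepted).
#' @return A `GenomeRef`.
#' @export
read_genome <- function(path) {
  ss <- readDNAStringSet(path)
  genome_ref(setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
}

#' Write a genome to FASTA
#' @param genome A `GenomeRef`.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  ss <- DNAStringSet(unlist(genome$sequences))
  names(ss) <- genome$chrom_names
  writeXStringSet(ss, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models and annotation sets
# ---------------------------------------------------------------------------

#' Construct a gene model
#'
#' Exons are stored in transcript orientation (rank 1 = 5' end); genomic
#' coordinates are 0-based half-open. `cds_span` is a 1-based inclusive
#' interval in transcript coordinates.
#'
#' @param gene_id Transcript/model identifier (unique within an annotation).
#' @param symbol Gene symbol.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (0-based half-open),
#'   ordered 5' to 3' in transcript orientation.
#' @param cds_span Optional `c(start, end)` in transcript coordinates.
#' @param biotype `"coding"` or `"noncoding"`.
#' @param sources Character vector of source tags.
#' @return A `GeneModel`.
#' @export
gene_model <- function(gene_id, symbol, chrom, strand, exons,
                       cds_span = NULL, biotype = c("coding", "noncoding"),
                       sources = "user") {
  biotype <- match.arg(biotype)
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)))
  if (any(exons$end <= exons$start)) stop("exon with end <= start in ", gene_id)
  exons <- exons[, c("start", "end")]
  exons$rank <- seq_len(nrow(exons))
  # transcript orientation: on -, genomic starts must be non-increasing
  if (nrow(exons) > 1L) {
    d <- diff(exons$start)
    ok <- if (strand == "+") all(d > 0) else all(d < 0)
    if (!ok) stop("exons of ", gene_id, " not ordered 5'->3' for strand ", strand)
  }
  # non-overlap check on genomic coordinates
  g <- exons[order(exons$start), ]
  if (nrow(g) > 1L && any(g$start[-1] < g$end[-nrow(g)])) {
    stop("overlapping exons in ", gene_id)
  }
  tlen <- sum(exons$end - exons$start)
  if (!is.null(cds_span)) {
    stopifnot(length(cds_span) == 2L)
    if (cds_span[1] < 1 || cds_span[2] > tlen || cds_span[1] > cds_span[2]) {
      stop("cds_span outside transcript length in ", gene_id)
    }
  }
  structure(list(gene_id = gene_id, symbol = symbol, chrom = chrom,
                 strand = strand, exons = exons, cds_span = cds_span,
                 biotype = biotype, sources = unique(sources),
                 tx_length = tlen),
            class = "GeneModel")
}

#' Transcript length of a model
#' @param model A `GeneModel`.
#' @export
tx_length <- function(model) model$tx_length

#' Genomic span of a model (0-based half-open)
#' @param model A `GeneModel`.
#' @return `c(start, end)`.
#' @export
gene_span <- function(model) {
  c(min(model$exons$start), max(model$exons$end))
}

#' Spliced transcript sequence of a model
#' @param model A `GeneModel`.
#' @param genome A `GenomeRef`.
#' @export
transcript_seq <- function(model, genome) {
  parts <- vapply(seq_len(nrow(model$exons)), function(i) {
    genome_seq(genome, model$chrom, model$exons$start[i], model$exons$end[i],
               model$strand)
  }, character(1))
  paste(parts, collapse = "")
}

.structure_key <- function(model) {
  paste(model$chrom, model$strand,
        paste(model$exons$start, model$exons$end, sep = "-", collapse = ";"),
        sep = "|")
}

#' Build an annotation set from gene models
#'
#' Models with identical (chromosome, strand, exon structure) are collapsed
#' into one record carrying the union of source tags. The set holds a
#' per-chromosome interval index over gene spans and an index of every exon
#' start/end for boundary queries.
#'
#' @param models List of `GeneModel` objects.
#' @return An `AnnotationSet`.
#' @export
annotation_set <- function(models) {
  stopifnot(length(models) > 0L)
  keys <- vapply(models, .structure_key, character(1))
  merged <- list()
  for (i in seq_along(models)) {
    k <- keys[i]
    if (is.null(merged[[k]])) {
      merged[[k]] <- models[[i]]
    } else {
      merged[[k]]$sources <- sort(unique(c(merged[[k]]$sources, models[[i]]$sources)))
      # keep the lexicographically smallest id for determinism
      if (models[[i]]$gene_id < merged[[k]]$gene_id) {
        keep_src <- merged[[k]]$sources
        merged[[k]] <- models[[i]]
        merged[[k]]$sources <- keep_src
      }
    }
  }
  models <- unname(merged)
  ids <- vapply(models, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) {
    # distinct structures sharing an id: suffix to keep ids unique
    ids <- make.unique(ids, sep = "#")
    for (i in seq_along(models)) models[[i]]$gene_id <- ids[i]
  }
  ord <- order(ids)
  models <- models[ord]
  ids <- ids[ord]
  names(models) <- ids

  spans <- t(vapply(models, gene_span, numeric(2)))
  gr <- GRanges(
    seqnames = vapply(models, `[[`, character(1), "chrom"),
    ranges = IRanges(start = spans[, 1] + 1L, end = spans[, 2]),
    strand = vapply(models, `[[`, character(1), "strand")
  )
  mcols(gr)$gene_id <- ids
  mcols(gr)$symbol <- vapply(models, `[[`, character(1), "symbol")
  mcols(gr)$biotype <- vapply(models, `[[`, character(1), "biotype")

  boundaries <- do.call(rbind, lapply(models, function(m) {
    data.frame(chrom = m$chrom, gene_id = m$gene_id, rank = m$exons$rank,
               # 1-based coordinates of the first and last base of each exon
               start1 = m$exons$start + 1L, end1 = m$exons$end,
               stringsAsFactors = FALSE)
  }))
  rownames(boundaries) <- NULL
  structure(list(genes = models, gr = gr, boundaries = boundaries),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:", length(x$genes), "gene models on",
      length(unique(as.character(GenomicRanges::seqnames(x$gr)))), "chromosome(s)\n")
  invisible(x)
}

#' Load and merge gene annotation from GTF and/or BED12 files
#'
#' Sources are merged by exact exon structure: models sharing (chromosome,
#' strand, exon structure) collapse into one record carrying all source tags,
#' so merging is idempotent and order-independent. Records with end <= start
#' are rejected and logged with a warning. Gzip input is accepted.
#'
#' @param paths Character vector of file paths.
#' @param dialects Character vector, one of `"gtf"` or `"bed12"` per path.
#' @param source_tags Optional tags per file (default: file base name).
#' @return An `AnnotationSet`.
#' @export
load_annotation <- function(paths, dialects, source_tags = basename(paths)) {
  stopifnot(length(paths) == length(dialects))
  models <- list()
  for (i in seq_along(paths)) {
    m <- switch(dialects[i],
      gtf = .parse_gtf(paths[i], source_tags[i]),
      bed12 = .parse_bed12(paths[i], source_tags[i]),
      stop("unknown dialect '", dialects[i], "'"))
    models <- c(models, m)
  }
  annotation_set(models)
}

.parse_gtf <- function(path, source_tag) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("parse error in '", path, "': ",
                                          conditionMessage(e)))
  df <- as.data.frame(gr)
  if (!nrow(df)) stop("no records in '", path, "'")
  bad <- df$width <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with end <= start rejected in '", path, "'")
    df <- df[!bad, , drop = FALSE]
  }
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (!nrow(ex)) stop("no exon records in '", path, "'")
  tx_ids <- unique(ex$transcript_id)
  lapply(tx_ids, function(tid) {
    e <- ex[ex$transcript_id == tid, , drop = FALSE]
    strand <- as.character(e$strand[1])
    e <- e[order(e$start, decreasing = (strand == "-")), ]
    exons <- data.frame(start = e$start - 1L, end = e$end)
    sym <- if (!is.null(e$gene_name) && !is.na(e$gene_name[1])) e$gene_name[1]
           else e$gene_id[1]
    cc <- cds[cds$transcript_id == tid, , drop = FALSE]
    cds_span <- NULL
    biotype <- "noncoding"
    if (nrow(cc)) {
      biotype <- "coding"
      cds_span <- .genomic_to_tx_span(exons, strand,
                                      min(cc$start) - 1L, max(cc$end))
    }
    gene_model(gene_id = tid, symbol = sym, chrom = as.character(e$seqnames[1]),
               strand = strand, exons = exons, cds_span = cds_span,
               biotype = biotype, sources = source_tag)
  })
}

.parse_bed12 <- function(path, source_tag) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("parse error in '", path, "': ",
                                          conditionMessage(e)))
  if (!length(gr)) stop("no records in '", path, "'")
  lapply(seq_along(gr), function(i) {
    r <- gr[i]
    strand <- as.character(GenomicRanges::strand(r))
    if (!strand %in% c("+", "-")) strand <- "+"
    blocks <- if (!is.null(mcols(r)$blocks)) mcols(r)$blocks[[1]] else NULL
    if (is.null(blocks) || !length(blocks)) {
      exons <- data.frame(start = start(r) - 1L, end = end(r))
    } else {
      abs_blocks <- IRanges::shift(blocks, start(r) - 1L)
      exons <- data.frame(start = start(abs_blocks) - 1L, end = end(abs_blocks))
    }
    exons <- exons[order(exons$start, decreasing = (strand == "-")), , drop = FALSE]
    thick <- mcols(r)$thick
    cds_span <- NULL
    biotype <- "noncoding"
    if (!is.null(thick) && IRanges::width(thick) > 1L) {
      biotype <- "coding"
      cds_span <- .genomic_to_tx_span(exons, strand,
                                      IRanges::start(thick) - 1L, IRanges::end(thick))
    }
    nm <- if (!is.null(mcols(r)$name)) mcols(r)$name else paste0("bed", i)
    gene_model(gene_id = nm, symbol = nm, chrom = as.character(GenomicRanges::seqnames(r)),
               strand = strand, exons = exons, cds_span = cds_span,
               biotype = biotype, sources = source_tag)
  })
}

# Map a genomic interval (0-based half-open) to transcript coordinates
# (1-based inclusive) given exons in transcript orientation.
.genomic_to_tx_span <- function(exons, strand, gstart, gend) {
  lens <- exons$end - exons$start
  offs <- cumsum(c(0, lens[-length(lens)]))
  pos <- c(NA_integer_, NA_integer_)
  # transcript position of a genomic base at 0-based coordinate g
  tx_of <- function(g) {
    for (i in seq_len(nrow(exons))) {
      if (g >= exons$start[i] && g < exons$end[i]) {
        within <- if (strand == "+") g - exons$start[i] else exons$end[i] - 1L - g
        return(offs[i] + within + 1L)
      }
    }
    NA_integer_
  }
  t1 <- tx_of(gstart)
  t2 <- tx_of(gend - 1L)
  if (is.na(t1) || is.na(t2)) return(NULL)
  sort(c(t1, t2))
}

#' Query the nearest known exon boundary
#'
#' Returns the exon whose start or end (1-based) lies within `tol` bases of
#' `pos`, or `NULL` if none. Ties break to the smallest distance, then the
#' lowest `gene_id`.
#'
#' @param annotation An `AnnotationSet`.
#' @param chrom Chromosome.
#' @param pos 1-based genomic coordinate.
#' @param tol Tolerance in bases (>= 0).
#' @return A list with `gene_id`, `rank`, `boundary` (1-based coordinate),
#'   `side` (`"start"`/`"end"`), `distance`; or `NULL`.
#' @export
is_known_exon_boundary <- function(annotation, chrom, pos, tol = 0L) {
  b <- annotation$boundaries
  if (!chrom %in% b$chrom) stop("unknown chromosome '", chrom, "'")
  b <- b[b$chrom == chrom, , drop = FALSE]
  cand <- rbind(
    data.frame(gene_id = b$gene_id, rank = b$rank, boundary = b$start1,
               side = "start", distance = abs(b$start1 - pos)),
    data.frame(gene_id = b$gene_id, rank = b$rank, boundary = b$end1,
               side = "end", distance = abs(b$end1 - pos))
  )
  cand <- cand[cand$distance <= tol, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(cand$distance, cand$gene_id, cand$side), , drop = FALSE]
  as.list(cand[1, ])
}

#' Are two genes immediate genomic neighbors?
#'
#' TRUE iff both genes lie on the same chromosome and no third distinct
#' gene's span lies strictly within the gap between their spans. Overlapping
#' spans count as adjacent. The relation is symmetric.
#'
#' @param a,b `GeneModel` objects (or gene ids resolvable in `annotation`).
#' @param annotation An `AnnotationSet` containing both.
#' @export
are_adjacent_genes <- function(a, b, annotation) {
  if (is.character(a)) a <- annotation$genes[[a]]
  if (is.character(b)) b <- annotation$genes[[b]]
  stopifnot(!is.null(a), !is.null(b))
  if (a$chrom != b$chrom) return(FALSE)
  sa <- gene_span(a); sb <- gene_span(b)
  gap <- c(min(sa[2], sb[2]), max(sa[1], sb[1]))  # 0-based half-open gap
  if (gap[1] >= gap[2]) return(TRUE)              # spans touch or overlap
  for (m in annotation$genes) {
    if (m$gene_id %in% c(a$gene_id, b$gene_id)) next
    if (m$chrom != a$chrom) next
    sm <- gene_span(m)
    if (sm[1] >= gap[1] && sm[2] <= gap[2]) return(FALSE)
  }
  TRUE
}

#' Genes overlapping a genomic position
#'
#' @param annotation An `AnnotationSet`.
#' @param chrom Chromosome.
#' @param pos 1-based coordinate.
#' @return Character vector of gene ids whose span overlaps `pos`.
#' @export
genes_at <- function(annotation, chrom, pos) {
  q <- GRanges(chrom, IRanges(pos, pos))
  hits <- findOverlaps(q, annotation$gr, ignore.strand = TRUE)
  sort(mcols(annotation$gr)$gene_id[subjectHits(hits)])
}

#' Choose the representative transcript of a gene symbol
#'
#' The longest coding transcript wins; ties break to the lowest gene id.
#' Falls back to the longest transcript of any biotype when no coding model
#' exists for the symbol.
#'
#' @param annotation An `AnnotationSet`.
#' @param symbol Gene symbol.
#' @return A `GeneModel`.
#' @export
choose_transcript <- function(annotation, symbol) {
  hits <- Filter(function(m) m$symbol == symbol, annotation$genes)
  if (!length(hits)) stop("no model with symbol '", symbol, "'")
  coding <- Filter(function(m) m$biotype == "coding", hits)
  pool <- if (length(coding)) coding else hits
  lens <- vapply(pool, tx_length, numeric(1))
  ids <- vapply(pool, `[[`, character(1), "gene_id")
  pool[[order(-lens, ids)[1]]]
}

# ---------------------------------------------------------------------------
# Cytobands
# ---------------------------------------------------------------------------

#' Read a cytoband table
#'
#' TSV with columns chrom, start (0-based), end, band, stain (UCSC
#' cytoBand.txt layout); gzip accepted. Bands per chromosome must be
#' non-overlapping; they are sorted on load.
#'
#' @param path File path.
#' @return A `CytobandTable` (data.frame with chrom, start, end, band).
#' @export
read_cytobands <- function(path) {
  df <- read.delim(if (grepl("\\.gz$", path)) gzfile(path) else path,
                   header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("cytoband table needs >= 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "band")
  cytoband_table(df[, 1:4])
}

#' Construct a cytoband table from a data.frame
#' @param df data.frame with chrom, start (0-based), end, band.
#' @export
cytoband_table <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "band") %in% names(df)))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    x <- df[df$chrom == ch, ]
    if (nrow(x) > 1L && any(x$start[-1] < x$end[-nrow(x)])) {
      stop("overlapping cytobands on ", ch)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("CytobandTable", "data.frame")
  df
}

#' Cytoband label at a genomic position
#'
#' Bands are half-open on their 0-based coordinates, so a 1-based position
#' equal to `start + 1` belongs to that band. The returned label joins the
#' chromosome (without any `chr` prefix) and the band, e.g. `"7p11"`.
#'
#' @param chrom Chromosome.
#' @param pos 1-based position.
#' @param table A `CytobandTable`.
#' @export
band_of <- function(chrom, pos, table) {
  x <- table[table$chrom == chrom & table$start < pos & pos <= table$end, ,
             drop = FALSE]
  if (nrow(x) != 1L) {
    stop("position ", chrom, ":", pos, " not covered by exactly one band")
  }
  paste0(sub("^chr", "", chrom), x$band[1])
}
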