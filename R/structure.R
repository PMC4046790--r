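# ---------------------------------------------------------------------------
# Chimeric transcript construction and protein structure classification.
# ---------------------------------------------------------------------------

# transcript-coordinate (1-based) position of a 1-based genomic boundary
# that coincides with an exon start or end of the model; "end" boundaries
# return the transcript offset of the exon's last base.
.tx_pos_of_boundary <- function(model, gpos) {
  lens <- model$exons$end - model$exons$start
  offs <- cumsum(c(0, lens[-length(lens)]))
  for (i in seq_len(nrow(model$exons))) {
    s1 <- model$exons$start[i] + 1L  # first base, 1-based
    e1 <- model$exons$end[i]         # last base, 1-based
    # transcript-orientation first/last base of this exon
    first <- if (model$strand == "+") s1 else e1
    last <- if (model$strand == "+") e1 else s1
    if (gpos == first) return(list(rank = i, tx = offs[i] + 1L, side = "first"))
    if (gpos == last) return(list(rank = i, tx = offs[i] + lens[i], side = "last"))
  }
  NULL
}

#' Build the chimeric transcript of a fusion
#'
#' The 5' side contributes the 5' gene's exons through the breakpoint in
#' transcript orientation (the 5' breakpoint must be the transcript-oriented
#' last base of one of its exons). The 3' side contributes the partner
#' transcript from its breakpoint exon onward when annotated, or
#' `uar_extension` bases of genomic sequence on the reported strand when the
#' partner is an unannotated region.
#'
#' @param fusion A list/row with `gene5`, `pos5`, `gene3` (symbol or
#'   `"UAR"`), `chrom3`, `pos3`, `strand3`.
#' @param annotation An `AnnotationSet`.
#' @param genome A `GenomeRef`.
#' @param uar_extension Genomic bases appended for a UAR partner
#'   (default 10000, clipped at the chromosome end).
#' @return A `ChimericTranscript`: `seq`, `junction` (1-based offset of the
#'   last 5' base), `five` (gene, model, exons retained, coding bases
#'   retained), `three` (gene or `"UAR"`, model or NULL, entry transcript
#'   position).
#' @export
build_chimeric <- function(fusion, annotation, genome, uar_extension = 10000L) {
  m5 <- choose_transcript(annotation, fusion$gene5)
  hit5 <- .tx_pos_of_boundary(m5, fusion$pos5)
  if (is.null(hit5) || hit5$side != "last") {
    stop("non-exonic 5' junction: ", fusion$gene5, " has no exon ending at ",
         fusion$pos5)
  }
  seq5 <- substr(transcript_seq(m5, genome), 1L, hit5$tx)

  if (identical(fusion$gene3, "UAR")) {
    chrom_len <- chrom_length(genome, fusion$chrom3)
    strand3 <- if (!is.null(fusion$strand3) && !is.na(fusion$strand3))
      fusion$strand3 else "+"
    if (strand3 == "+") {
      s0 <- fusion$pos3 - 1L
      e0 <- min(chrom_len, s0 + uar_extension)
    } else {
      e0 <- fusion$pos3
      s0 <- max(0L, e0 - uar_extension)
    }
    seq3 <- genome_seq(genome, fusion$chrom3, s0, e0, strand3)
    three <- list(gene = "UAR", model = NULL, entry_tx = NA_integer_)
  } else {
    m3 <- choose_transcript(annotation, fusion$gene3)
    hit3 <- .tx_pos_of_boundary(m3, fusion$pos3)
    if (is.null(hit3)) {
      stop("3' breakpoint of ", fusion$gene3, " not at an exon boundary: ",
           fusion$pos3)
    }
    entry <- if (hit3$side == "first") hit3$tx else hit3$tx  # tx offset of entry base
    seq3 <- substring(transcript_seq(m3, genome), entry)
    three <- list(gene = fusion$gene3, model = m3, entry_tx = entry)
  }

  cds <- m5$cds_span
  coding_retained <- if (is.null(cds)) 0L else
    max(0L, min(hit5$tx, cds[2]) - cds[1] + 1L)
  structure(list(
    seq = paste0(seq5, seq3),
    junction = hit5$tx,
    five = list(gene = fusion$gene5, model = m5, exons_retained = hit5$rank,
                coding_retained = coding_retained),
    three = three
  ), class = "ChimericTranscript")
}

#' @export
print.ChimericTranscript <- function(x, ...) {
  cat("ChimericTranscript:", nchar(x$seq), "bp;", x$five$gene, "->",
      x$three$gene, "; junction after base", x$junction, "\n")
  invisible(x)
}

.translate_from <- function(seq, start) {
  if (start > nchar(seq)) return("")
  s <- substring(seq, start)
  s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
  if (!nchar(s)) return("")
  aa <- as.character(translate(DNAString(s), if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", aa, fixed = TRUE)[1]
  if (stop_at > 0) substr(aa, 1L, stop_at - 1L) else aa
}

.longest_orf <- function(seq, min_orf) {
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  best <- ""
  if (starts[1] < 0) return(best)
  for (s in starts) {
    pep <- .translate_from(seq, s)
    if (nchar(pep) > nchar(best)) best <- pep
  }
  if (nchar(best) >= min_orf) best else ""
}

#' Classify the predicted protein structure of a chimeric transcript
#'
#' Decision rules (in order):
#'
#' * 5' partner noncoding: `no_protein` (empty peptide unless an open
#'   reading frame of at least `min_orf` codons exists, which is then
#'   reported without changing the class).
#' * Junction upstream of the 5' CDS start with an annotated coding 3'
#'   partner: `promoter_swap_full` when the entire 3' CDS is retained (the
#'   5' gene lends only its promoter/5' UTR), else
#'   `promoter_swap_n_truncated`.
#' * Annotated noncoding 3' partner: `noncoding_truncation` (C-terminal
#'   truncation of the 5' protein by fusion with a non-coding RNA).
#' * Both partners coding, junction inside the 5' CDS: `in_frame` when the
#'   retained 5' coding length matches the 3' entry codon phase and
#'   translation reaches the 3' CDS without a stop; otherwise
#'   `out_of_frame`.
#' * UAR 3' partner: `extended_3utr` when the whole 5' CDS is retained (the
#'   appended sequence only lengthens the 3' UTR), else `truncated_gene`
#'   (translation runs off the junction into unannotated sequence and stops).
#'
#' The predicted peptide is always obtained by translating the chimeric
#' sequence from the 5' start codon to the first stop.
#'
#' @param chimeric A `ChimericTranscript`.
#' @param min_orf Minimum ORF length (codons) to report any peptide for a
#'   noncoding 5' partner (default 50).
#' @return A `StructureCall`: `class`, `peptide`, `frame_shift`.
#' @export
classify_structure <- function(chimeric, min_orf = 50L) {
  m5 <- chimeric$five$model
  three <- chimeric$three
  jc <- chimeric$junction
  result <- function(class, peptide = "", frame_shift = NA) {
    structure(list(class = class, peptide = peptide, frame_shift = frame_shift),
              class = "StructureCall")
  }

  if (m5$biotype != "coding" || is.null(m5$cds_span)) {
    if (m5$biotype == "coding") stop("missing CDS annotation on coding model ",
                                     m5$gene_id)
    return(result("no_protein", .longest_orf(chimeric$seq, min_orf)))
  }
  cds5 <- m5$cds_span
  pep <- .translate_from(chimeric$seq, cds5[1])

  partner_coding <- !is.null(three$model) && three$model$biotype == "coding" &&
    !is.null(three$model$cds_span)
  if (!is.null(three$model) && three$model$biotype == "coding" &&
      is.null(three$model$cds_span)) {
    stop("missing CDS annotation on coding model ", three$model$gene_id)
  }

  if (jc < cds5[1]) {
    # 5' gene contributes only promoter / 5' UTR
    if (partner_coding) {
      cds3 <- three$model$cds_span
      if (three$entry_tx <= cds3[1]) {
        pep3 <- .translate_from(chimeric$seq,
                                jc + (cds3[1] - three$entry_tx) + 1L)
        return(result("promoter_swap_full", pep3, FALSE))
      }
      return(result("promoter_swap_n_truncated",
                    .longest_orf(chimeric$seq, 1L), FALSE))
    }
    return(result("no_protein", .longest_orf(chimeric$seq, min_orf)))
  }

  if (!is.null(three$model) && three$model$biotype == "noncoding") {
    return(result("noncoding_truncation", pep, NA))
  }

  if (partner_coding) {
    cds3 <- three$model$cds_span
    c5 <- chimeric$five$coding_retained
    entry_into_cds <- three$entry_tx - cds3[1]  # bases of 3' CDS skipped
    phase_ok <- entry_into_cds >= 0 && (c5 %% 3L) == (entry_into_cds %% 3L)
    # peptide must reach past the junction for a true chimeric product
    pep_len_to_junction <- (jc - cds5[1] + 1L) %/% 3L
    crosses <- nchar(pep) > pep_len_to_junction
    if (phase_ok && crosses) return(result("in_frame", pep, FALSE))
    return(result("out_of_frame", pep, TRUE))
  }

  # UAR partner
  if (jc >= cds5[2]) {
    return(result("extended_3utr", pep, FALSE))
  }
  result("truncated_gene", pep, NA)
}

#' @export
print.StructureCall <- function(x, ...) {
  cat("StructureCall:", x$class, "- peptide", nchar(x$peptide), "aa\n")
  invisible(x)
}

#' Does the predicted fusion peptide retain a complete kinase domain?
#'
#' TRUE iff the peptide contains, unbroken, the full amino-acid image of an
#' annotated domain interval from either partner protein. Domain intervals
#' are user input (protein coordinates plus the partner's protein sequence);
#' no homology search is performed.
#'
#' @param call A `StructureCall`.
#' @param domains data.frame with columns `gene`, `domain`, `aa_start`,
#'   `aa_end`, `protein` (the partner's full protein sequence).
#' @return Logical; FALSE with a warning when no domain annotation exists
#'   for either partner.
#' @export
kinase_domain_retained <- function(call, domains) {
  if (is.null(domains) || !nrow(domains)) {
    warning("no domain annotation for either partner")
    return(FALSE)
  }
  for (i in seq_len(nrow(domains))) {
    img <- substr(domains$protein[i], domains$aa_start[i], domains$aa_end[i])
    if (nchar(img) == domains$aa_end[i] - domains$aa_start[i] + 1L &&
        grepl(img, call$peptide, fixed = TRUE)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Translate a gene model's CDS to protein
#' @param model A coding `GeneModel`.
#' @param genome A `GenomeRef`.
#' @export
protein_seq <- function(model, genome) {
  if (is.null(model$cds_span)) stop("model ", model$gene_id, " has no CDS")
  tx <- transcript_seq(model, genome)
  .translate_from(tx, model$cds_span[1])
}

#' Write peptides as FASTA
#' @param peptides Named character vector.
#' @param path Output path.
#' @export
write_peptides <- function(peptides, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(peptides), "\n", peptides), con)
  invisible(path)
}
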