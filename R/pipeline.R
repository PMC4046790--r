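# ---------------------------------------------------------------------------
# End-to-end drivers chaining the discovery and annotation stages.
# ---------------------------------------------------------------------------

#' Discovery pipeline: expression outliers to fusion candidates
#'
#' Chains the single-end discovery stages: exon RPKM -> COPA outlier
#' z-scores -> candidate (gene, sample) selection -> exon-walking breakpoint
#' detection -> extraction of partially mapped color-space reads ->
#' consensus assembly -> split alignment -> junction support counting.
#' Genes whose walk shows an expression drop are pursued as 5' anchors; the
#' matching rise in the 3' partner is the mirror image of the same junction.
#'
#' @param genome A `GenomeRef`.
#' @param annotation An `AnnotationSet`.
#' @param matrix An `ExonExpressionMatrix`.
#' @param reads data.frame of aligned color-space reads (columns `sample`,
#'   `id`, `gene_id`, `boundary`, `primer`, `colors`, `matched_length`).
#' @param params List of thresholds; defaults follow the pipeline
#'   configuration: `trim_fraction` 0.75, `z_min` 4, `rpkm_min` 20,
#'   `fold` 2, `quantile` 0.70, `max_exon_match` 35, `min_anchor` 10,
#'   `min_support` 2, `max_mismatch_frac` 0.1, `min_part_len` 20,
#'   `min_margin` 8.
#' @param verbose Log per-stage record counts to stderr.
#' @return list with `candidates` (fusion candidate table), `copa`,
#'   `selected`, `stage_counts`.
#' @export
run_discover <- function(genome, annotation, matrix, reads,
                         params = list(), verbose = FALSE) {
  p <- utils::modifyList(list(
    trim_fraction = 0.75, z_min = 4, rpkm_min = 20, fold = 2,
    quantile = 0.70, max_exon_match = 35L, min_anchor = 10L,
    min_support = 2L, max_mismatch_frac = 0.1, min_part_len = 20L,
    min_margin = 8), params)
  log <- function(...) if (verbose) message("[discover] ", ...)

  copa <- copa_z(matrix, p$trim_fraction, p$z_min)
  selected <- select_candidate_genes(copa, matrix, p$rpkm_min)
  log(nrow(selected), " candidate gene/sample pairs")

  candidates <- list()
  n_bp <- 0L
  for (i in seq_len(nrow(selected))) {
    gid <- selected$gene_id[i]
    smp <- selected$sample[i]
    model <- annotation$genes[[gid]]
    bps <- walk_breakpoints(matrix, model, smp, p$fold, p$quantile)
    bps <- bps[bps$direction == "drop", , drop = FALSE]
    n_bp <- n_bp + nrow(bps)
    for (j in seq_len(nrow(bps))) {
      boundary <- .exon_last_gpos(model, bps$rank5[j])
      pool <- reads[reads$sample == smp & reads$gene_id == gid, , drop = FALSE]
      partial <- extract_partial_reads(pool, boundary,
                                       p$max_exon_match, p$min_anchor)
      if (nrow(partial) < p$min_support) next
      consensi <- build_consensus(partial, p$min_support, p$max_mismatch_frac)
      for (cons in consensi) {
        cand <- split_align(cons, genome, annotation, model, boundary,
                            sample = smp, min_part_len = p$min_part_len,
                            min_margin = p$min_margin)
        if (!is.data.frame(cand)) next
        # junction support: count sample reads of this gene against the
        # consensus junction window and the wild-type junction
        pool_bases <- vapply(seq_len(nrow(pool)), function(k) {
          decode_colors(pool$primer[k], pool$colors[k], policy = "truncate")
        }, character(1))
        wt5 <- NA_integer_
        if (bps$rank5[j] < nrow(model$exons)) {
          tx <- transcript_seq(model, genome)
          jc <- .tx_cum(model)[bps$rank5[j]]
          lo <- max(1L, jc - 60L)
          w5 <- substr(tx, lo, min(nchar(tx), jc + 60L))
          wt5 <- count_junction_support(pool_bases, cand$fusion_seq,
                                        cons$junction_col,
                                        wt5_window = w5,
                                        wt5_junction = jc - lo + 1L,
                                        min_anchor = p$min_anchor)$wt5
        }
        cand$wt5 <- wt5
        cand$wt3 <- NA_integer_
        candidates[[length(candidates) + 1L]] <- cand
      }
    }
  }
  log(n_bp, " walk breakpoints pursued; ", length(candidates), " candidates")
  tab <- if (length(candidates)) {
    out <- do.call(rbind, candidates)
    rownames(out) <- NULL
    out
  } else {
    data.frame(sample = character(0), gene5 = character(0),
               chrom5 = character(0), strand5 = character(0),
               pos5 = numeric(0), gene3 = character(0),
               chrom3 = character(0), strand3 = character(0),
               pos3 = numeric(0), partner_class = character(0),
               junction_reads = integer(0), identity3 = numeric(0),
               margin = numeric(0), fusion_seq = character(0),
               source = character(0), wt5 = integer(0), wt3 = integer(0))
  }
  list(candidates = tab, copa = copa, selected = selected,
       stage_counts = c(selected = nrow(selected), breakpoints = n_bp,
                        candidates = nrow(tab)))
}

#' Annotation pipeline: curation, mechanism, structure, cohort summary
#'
#' @param records Caller-record data.frame (see [read_caller_records()] /
#'   [merge_caller_records()]).
#' @param annotation An `AnnotationSet`.
#' @param genome A `GenomeRef` (NULL skips structure prediction).
#' @param copa A `CopaResult` or NULL.
#' @param wt_counts data.frame `wt5`, `wt3` per record.
#' @param segsets Named list of `SegmentSet` per sample; NULL skips
#'   mechanism classification (label `"unclassified"`).
#' @param pmap A `PatientMap` (built from the record samples when NULL).
#' @param params A `CurationParams`.
#' @param mech_params List of `window`, `amp_log2`, `del_delta` overrides.
#' @return list with `curated` (audited table), `retained`, `mechanisms`,
#'   `structures`, `summary`.
#' @export
run_annotate <- function(records, annotation, genome = NULL, copa = NULL,
                         wt_counts = NULL, segsets = NULL, pmap = NULL,
                         params = curation_params(), mech_params = list()) {
  if (is.null(wt_counts)) {
    wt_counts <- data.frame(wt5 = rep(NA_real_, nrow(records)),
                            wt3 = rep(NA_real_, nrow(records)))
  }
  curated <- apply_curation(records, annotation, copa, wt_counts, params)
  retained <- curated[curated$retained, , drop = FALSE]

  mp <- utils::modifyList(list(window = 30000, amp_log2 = 0.9,
                               del_delta = 0.3), mech_params)
  mechanisms <- rep(NA_character_, nrow(retained))
  if (!is.null(segsets) && nrow(retained)) {
    for (i in seq_len(nrow(retained))) {
      ss <- segsets[[retained$sample[i]]]
      if (is.null(ss)) next
      mechanisms[i] <- classify_mechanism(retained[i, ], ss, mp$window,
                                          mp$amp_log2, mp$del_delta)$label
    }
  } else if (nrow(retained)) {
    mechanisms <- rep("unclassified", nrow(retained))
  }

  structures <- rep(NA_character_, nrow(retained))
  if (!is.null(genome) && nrow(retained)) {
    for (i in seq_len(nrow(retained))) {
      sc <- tryCatch({
        chim <- build_chimeric(retained[i, ], annotation, genome)
        classify_structure(chim)$class
      }, error = function(e) NA_character_)
      structures[i] <- sc
    }
  }

  if (is.null(pmap)) pmap <- build_patient_map(unique(records$sample))
  summary <- if (nrow(retained)) {
    summarize_cohort(retained, pmap, mechanisms = mechanisms,
                     structures = structures)
  } else NULL
  list(curated = curated, retained = retained, mechanisms = mechanisms,
       structures = structures, summary = summary)
}

#' Write the candidate table as TSV
#' @param candidates Candidate table from [run_discover()].
#' @param path Output path.
#' @export
write_candidates <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
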