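# ---------------------------------------------------------------------------
# External fusion-caller dialects and the six-rule curation filter.
#
# Caller record columns (the unified CallerRecord layout):
#   sample, gene5, gene3, chrom5, pos5, strand5, chrom3, pos3, strand3,
#   orient5, orient3 (f/r: whether the transcript runs toward the breakpoint
#   in genomic forward or reverse direction), span_reads, span_pairs,
#   caller, candidate_only
# ---------------------------------------------------------------------------

.caller_record_cols <- c("sample", "gene5", "gene3", "chrom5", "pos5",
                         "strand5", "chrom3", "pos3", "strand3",
                         "orient5", "orient3", "span_reads", "span_pairs",
                         "caller", "candidate_only")

#' Curation parameter set
#'
#' Defaults mirror the published filter: spanning/wild-type ratio strictly
#' greater than 2; spanning reads at least 100 or partner outlier z at least
#' 5; candidate-only records (present in the caller's unfiltered candidate
#' list but not its final report) need partner z at least 10; the
#' normal-tissue blacklist carries the TFG->GPR128 pair.
#'
#' @param min_ratio Spanning vs wild-type ratio threshold (strict >).
#' @param min_span Spanning-read threshold (>=).
#' @param z_pass Outlier z threshold for the span-or-z rule (>=).
#' @param z_candidate_only Outlier z required of candidate-only records (>=).
#' @param blacklist data.frame `gene5`, `gene3` of pairs seen in normal
#'   tissues.
#' @param boundary_tol Exon-boundary matching tolerance in bases.
#' @return A `CurationParams` list.
#' @export
curation_params <- function(min_ratio = 2, min_span = 100, z_pass = 5,
                            z_candidate_only = 10,
                            blacklist = data.frame(gene5 = "TFG",
                                                   gene3 = "GPR128"),
                            boundary_tol = 0L) {
  stopifnot(min_ratio > 0, min_span > 0, z_pass > 0, z_candidate_only > 0)
  structure(list(min_ratio = min_ratio, min_span = min_span, z_pass = z_pass,
                 z_candidate_only = z_candidate_only, blacklist = blacklist,
                 boundary_tol = as.integer(boundary_tol)),
            class = "CurationParams")
}

#' Read an external fusion-caller output file
#'
#' Supported dialects (tab-separated, one record per line, `#` comments
#' ignored, gzip accepted):
#'
#' * `tophatfusion_potential` — the caller's unfiltered candidate list:
#'   `sample  chromA-chromB  posA  posB  orient  span_reads  span_pairs`
#'   (orient is two characters, f/r per side; gene symbols are absent in
#'   this layout and left NA for later resolution against an annotation).
#' * `tophatfusion_result` — the caller's final report:
#'   `sample  gene5  chrom5  pos5  gene3  chrom3  pos3  span_reads
#'   span_pairs  orient`
#' * `snowshoes` — final fusion report:
#'   `sample  gene5  chrom5  pos5  strand5  gene3  chrom3  pos3  strand3
#'   span_reads  isoform`
#'
#' Coordinates are normalized to 1-based. Records read from the potential
#' list carry `candidate_only = TRUE` until reconciled against the result
#' file with [merge_caller_records()].
#'
#' @param path File path.
#' @param dialect One of `"tophatfusion_potential"`, `"tophatfusion_result"`,
#'   `"snowshoes"`.
#' @return data.frame of caller records.
#' @export
read_caller_records <- function(path, dialect = c("tophatfusion_potential",
                                                  "tophatfusion_result",
                                                  "snowshoes")) {
  dialect <- match.arg(dialect)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(.empty_records())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  expected <- switch(dialect, tophatfusion_potential = 7L,
                     tophatfusion_result = 10L, snowshoes = 11L)
  bad <- which(nf != expected)
  if (length(bad)) {
    stop("dialect error in '", path, "' (", dialect, "): expected ",
         expected, " columns, got ", nf[bad[1]], " at line: ", lines[bad[1]])
  }
  recs <- lapply(fields, function(f) {
    switch(dialect,
      tophatfusion_potential = {
        chroms <- strsplit(f[2], "-", fixed = TRUE)[[1]]
        orient <- strsplit(f[5], "", fixed = TRUE)[[1]]
        data.frame(sample = f[1], gene5 = NA_character_, gene3 = NA_character_,
                   chrom5 = chroms[1], pos5 = as.numeric(f[3]),
                   strand5 = NA_character_,
                   chrom3 = chroms[2], pos3 = as.numeric(f[4]),
                   strand3 = NA_character_,
                   orient5 = orient[1], orient3 = orient[2],
                   span_reads = as.numeric(f[6]), span_pairs = as.numeric(f[7]),
                   caller = "tophatfusion", candidate_only = TRUE)
      },
      tophatfusion_result = {
        orient <- strsplit(f[10], "", fixed = TRUE)[[1]]
        data.frame(sample = f[1], gene5 = f[2], gene3 = f[5],
                   chrom5 = f[3], pos5 = as.numeric(f[4]),
                   strand5 = NA_character_,
                   chrom3 = f[6], pos3 = as.numeric(f[7]),
                   strand3 = NA_character_,
                   orient5 = orient[1], orient3 = orient[2],
                   span_reads = as.numeric(f[8]), span_pairs = as.numeric(f[9]),
                   caller = "tophatfusion", candidate_only = FALSE)
      },
      snowshoes = {
        data.frame(sample = f[1], gene5 = f[2], gene3 = f[6],
                   chrom5 = f[3], pos5 = as.numeric(f[4]), strand5 = f[5],
                   chrom3 = f[7], pos3 = as.numeric(f[8]), strand3 = f[9],
                   orient5 = ifelse(f[5] == "+", "f", "r"),
                   orient3 = ifelse(f[9] == "+", "f", "r"),
                   span_reads = as.numeric(f[10]), span_pairs = NA_real_,
                   caller = "snowshoes", candidate_only = NA)
      })
  })
  out <- do.call(rbind, recs)
  if (any(is.na(out$span_reads)) || any(out$span_reads < 0, na.rm = TRUE)) {
    stop("dialect error in '", path, "': non-numeric or negative span_reads")
  }
  out
}

.empty_records <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), length(.caller_record_cols)),
                               .caller_record_cols))
  for (col in c("pos5", "pos3", "span_reads", "span_pairs")) df[[col]] <- numeric(0)
  df$candidate_only <- logical(0)
  df
}

#' Merge caller record lists across sources
#'
#' Records with the same sample and gene pair whose breakpoints both lie
#' within `tol` bases collapse into one record: provenance is the union of
#' callers, spanning reads the maximum over sources, and `candidate_only`
#' only remains TRUE when every merged source was candidate-only (a record
#' present in a final report is not candidate-only). Gene symbols fill in
#' from whichever source has them.
#'
#' @param lists A list of caller-record data.frames.
#' @param tol Breakpoint matching tolerance in bases.
#' @return Unified data.frame of caller records.
#' @export
merge_caller_records <- function(lists, tol = 10L) {
  all <- do.call(rbind, lists)
  if (is.null(all) || !nrow(all)) return(.empty_records())
  all$.row <- seq_len(nrow(all))
  merged <- list()
  used <- logical(nrow(all))
  for (i in seq_len(nrow(all))) {
    if (used[i]) next
    grp <- i
    for (j in seq_len(nrow(all))) {
      if (j == i || used[j]) next
      same_pair <- all$sample[i] == all$sample[j] &&
        all$chrom5[i] == all$chrom5[j] && all$chrom3[i] == all$chrom3[j] &&
        abs(all$pos5[i] - all$pos5[j]) <= tol &&
        abs(all$pos3[i] - all$pos3[j]) <= tol
      genes_known <- !is.na(all$gene5[i]) && !is.na(all$gene5[j])
      if (genes_known) {
        same_pair <- same_pair && all$gene5[i] == all$gene5[j] &&
          all$gene3[i] == all$gene3[j]
      }
      if (same_pair) grp <- c(grp, j)
    }
    used[grp] <- TRUE
    g <- all[grp, , drop = FALSE]
    rec <- g[1, , drop = FALSE]
    pick <- function(col) {
      v <- g[[col]]
      v <- v[!is.na(v)]
      if (length(v)) v[1] else NA
    }
    for (col in c("gene5", "gene3", "strand5", "strand3", "orient5", "orient3")) {
      rec[[col]] <- pick(col)
    }
    rec$span_reads <- max(g$span_reads, na.rm = TRUE)
    rec$span_pairs <- if (all(is.na(g$span_pairs))) NA_real_ else
      max(g$span_pairs, na.rm = TRUE)
    rec$caller <- paste(sort(unique(g$caller)), collapse = ",")
    co <- g$candidate_only
    rec$candidate_only <- if (all(is.na(co))) NA else all(co[!is.na(co)])
    rec$.row <- NULL
    merged[[length(merged) + 1L]] <- rec
  }
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Fill missing gene symbols by annotation overlap
#'
#' Caller dialects without gene columns (the unfiltered candidate list) get
#' symbols assigned from the gene model overlapping each breakpoint (the
#' alphabetically first symbol when several overlap; `NA` stays when none).
#'
#' @param records Caller-record data.frame.
#' @param annotation An `AnnotationSet`.
#' @export
resolve_genes <- function(records, annotation) {
  fill <- function(chrom, pos) {
    ids <- tryCatch(genes_at(annotation, chrom, pos), error = function(e) character(0))
    if (!length(ids)) return(NA_character_)
    sort(vapply(ids, function(id) annotation$genes[[id]]$symbol, character(1)))[1]
  }
  for (i in seq_len(nrow(records))) {
    if (is.na(records$gene5[i])) {
      records$gene5[i] <- fill(records$chrom5[i], records$pos5[i])
    }
    if (is.na(records$gene3[i])) {
      records$gene3[i] <- fill(records$chrom3[i], records$pos3[i])
    }
  }
  records
}

# max COPA z over all exons of both partner genes in the record's sample;
# -Inf when neither gene is covered
.max_partner_z <- function(record, copa, symbol_index) {
  if (is.null(copa)) return(-Inf)
  genes <- c(record$gene5, record$gene3)
  genes <- genes[!is.na(genes) & genes != "UAR"]
  ids <- unlist(symbol_index[genes], use.names = FALSE)
  if (!length(ids)) return(-Inf)
  rows <- which(copa$exons$gene_id %in% ids)
  if (!length(rows) || !record$sample %in% colnames(copa$z)) return(-Inf)
  max(copa$z[rows, record$sample])
}

#' Apply the six-rule curation filter to caller records
#'
#' A record is retained iff all applicable rules hold:
#'
#' 1. At least one breakpoint is a known exon boundary (within
#'    `params$boundary_tol`).
#' 2. The spanning/wild-type read ratio is strictly greater than
#'    `params$min_ratio` for at least one partner; a wild-type count of 0
#'    (or NA, e.g. an unannotated partner with no wild-type junction) passes.
#' 3. Spanning reads are at least `params$min_span` OR the maximum partner
#'    outlier z is at least `params$z_pass`.
#' 4. Candidate-only records additionally need maximum partner z at least
#'    `params$z_candidate_only`.
#' 5. The fusion maintains 5' to 3' transcript orientation: on each side the
#'    caller's junction orientation must agree with the gene strand
#'    (`f` with `+`, `r` with `-`); sides with unknown strand are not
#'    informative and pass.
#' 6. The gene pair is not on the normal-tissue blacklist.
#'
#' Fusions of adjacent genes (immediate genomic neighbors) are additionally
#' discarded. Every input record appears exactly once in the audited output
#' with one logical column per rule.
#'
#' @param records Caller-record data.frame.
#' @param annotation An `AnnotationSet`.
#' @param copa A `CopaResult` covering the partner genes (NULL disables the
#'   z-based rules; records then rely on spanning reads).
#' @param wt_counts data.frame with `wt5`, `wt3` (one row per record;
#'   NA where no wild-type junction exists).
#' @param params A `CurationParams`.
#' @return data.frame: the input records plus audit columns
#'   `rule1_boundary` .. `rule6_blacklist`, `not_adjacent`, `max_z`,
#'   `retained`.
#' @export
apply_curation <- function(records, annotation, copa, wt_counts,
                           params = curation_params()) {
  stopifnot(nrow(records) == nrow(wt_counts))
  n <- nrow(records)
  symbol_index <- split(names(annotation$genes),
                        vapply(annotation$genes, `[[`, character(1), "symbol"))
  symbol_models <- lapply(symbol_index, function(ids) annotation$genes[[ids[1]]])

  rule1 <- rule2 <- rule3 <- rule4 <- rule5 <- rule6 <- adj_ok <- logical(n)
  max_z <- numeric(n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    b5 <- tryCatch(!is.null(is_known_exon_boundary(annotation, r$chrom5, r$pos5,
                                                   params$boundary_tol)),
                   error = function(e) FALSE)
    b3 <- tryCatch(!is.null(is_known_exon_boundary(annotation, r$chrom3, r$pos3,
                                                   params$boundary_tol)),
                   error = function(e) FALSE)
    rule1[i] <- b5 || b3

    ratio_pass <- function(wt) {
      if (is.na(wt) || wt == 0) return(TRUE)
      r$span_reads / wt > params$min_ratio
    }
    rule2[i] <- ratio_pass(wt_counts$wt5[i]) || ratio_pass(wt_counts$wt3[i])

    max_z[i] <- .max_partner_z(r, copa, symbol_index)
    rule3[i] <- r$span_reads >= params$min_span || max_z[i] >= params$z_pass
    rule4[i] <- if (isTRUE(r$candidate_only)) max_z[i] >= params$z_candidate_only else TRUE

    side_ok <- function(gene, orient) {
      if (is.na(gene) || gene == "UAR" || is.na(orient)) return(TRUE)
      m <- symbol_models[[gene]]
      if (is.null(m)) return(TRUE)
      (m$strand == "+") == (orient == "f")
    }
    rule5[i] <- side_ok(r$gene5, r$orient5) && side_ok(r$gene3, r$orient3)

    bl <- params$blacklist
    rule6[i] <- !(any(!is.na(r$gene5) & !is.na(r$gene3) &
                      bl$gene5 == r$gene5 & bl$gene3 == r$gene3))

    m5 <- if (is.na(r$gene5)) NULL else symbol_models[[r$gene5]]
    m3 <- if (is.na(r$gene3)) NULL else symbol_models[[r$gene3]]
    adj_ok[i] <- if (is.null(m5) || is.null(m3) || identical(m5$gene_id, m3$gene_id)) TRUE
                 else !are_adjacent_genes(m5, m3, annotation)
  }
  out <- records
  out$max_z <- max_z
  out$rule1_boundary <- rule1
  out$rule2_ratio <- rule2
  out$rule3_support <- rule3
  out$rule4_candidate_only <- rule4
  out$rule5_orientation <- rule5
  out$rule6_blacklist <- rule6
  out$not_adjacent <- adj_ok
  out$retained <- rule1 & rule2 & rule3 & rule4 & rule5 & rule6 & adj_ok
  class(out) <- c("CuratedFusionTable", "data.frame")
  out
}

#' Write a curated fusion table as TSV (one audit column per rule)
#' @param curated Output of [apply_curation()].
#' @param path Output path.
#' @export
write_curated <- function(curated, path) {
  write.table(as.data.frame(curated), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
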