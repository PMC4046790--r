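# ---------------------------------------------------------------------------
# Cohort-level recurrence, distances, mechanism/structure distributions and
# association tests.
# ---------------------------------------------------------------------------

#' Build a sample-to-patient map
#'
#' TCGA barcodes collapse at the participant field (first three dash-
#' separated fields, e.g. `TCGA-06-0211-01A` -> `TCGA-06-0211`), so portion
#' and aliquot suffixes (-01A/-01B/-02A) never split a patient. Explicit
#' alias pairs map additional sample ids (e.g. internal cohort ids) onto the
#' same patient.
#'
#' @param samples Character vector of sample ids.
#' @param aliases Optional data.frame with columns `sample`, `patient`
#'   mapping non-TCGA ids to a patient id.
#' @return A `PatientMap`: named character vector sample -> patient, with a
#'   `cohort` attribute (`"tcga"`/`"other"` per sample).
#' @export
build_patient_map <- function(samples, aliases = NULL) {
  samples <- unique(samples)
  patient <- character(length(samples))
  cohort <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    if (!is.null(aliases) && s %in% aliases$sample) {
      patient[i] <- aliases$patient[match(s, aliases$sample)]
      cohort[i] <- "other"
    } else if (grepl("^TCGA-", s)) {
      patient[i] <- paste(strsplit(s, "-", fixed = TRUE)[[1]][1:3], collapse = "-")
      cohort[i] <- "tcga"
    } else {
      patient[i] <- s
      cohort[i] <- "other"
    }
  }
  structure(setNames(patient, samples), cohort = setNames(cohort, samples),
            class = "PatientMap")
}

.patient_of <- function(pmap, samples) {
  out <- unclass(pmap)[samples]
  if (anyNA(out)) {
    stop("sample(s) missing from patient map: ",
         paste(unique(samples[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Genes that partner in fusions of more than one patient
#'
#' Counts, per gene symbol, the number of distinct patients with at least one
#' fusion involving that gene (as either partner). A gene occurring in
#' several fusions or aliquots of the same patient counts once; the `"UAR"`
#' placeholder (unannotated region) is never counted as a gene. Only genes
#' seen in two or more patients are returned.
#'
#' @param fusions data.frame with columns `sample`, `gene5`, `gene3`.
#' @param pmap A `PatientMap` covering every sample.
#' @return data.frame `gene`, `n_patients`, sorted by descending count then
#'   gene.
#' @export
recurrent_partner_genes <- function(fusions, pmap) {
  pat <- .patient_of(pmap, fusions$sample)
  long <- rbind(data.frame(gene = fusions$gene5, patient = pat),
                data.frame(gene = fusions$gene3, patient = pat))
  long <- long[long$gene != "UAR", , drop = FALSE]
  long <- unique(long)
  tab <- table(long$gene)
  tab <- tab[tab >= 2L]
  out <- data.frame(gene = names(tab), n_patients = as.integer(tab))
  out <- out[order(-out$n_patients, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Patients per fusion gene pair
#'
#' @param fusions data.frame with `sample`, `gene5`, `gene3`.
#' @param pmap A `PatientMap`.
#' @param cohort Optional filter: `"tcga"` or `"other"` restricts to samples
#'   of that cohort before counting.
#' @return data.frame `gene5`, `gene3`, `n_patients`.
#' @export
fusion_pair_patients <- function(fusions, pmap, cohort = NULL) {
  if (!is.null(cohort)) {
    co <- attr(pmap, "cohort")[fusions$sample]
    fusions <- fusions[!is.na(co) & co == cohort, , drop = FALSE]
  }
  if (!nrow(fusions)) {
    return(data.frame(gene5 = character(0), gene3 = character(0),
                      n_patients = integer(0)))
  }
  pat <- .patient_of(pmap, fusions$sample)
  key <- unique(data.frame(gene5 = fusions$gene5, gene3 = fusions$gene3,
                           patient = pat))
  agg <- aggregate(patient ~ gene5 + gene3, data = key, FUN = length)
  names(agg)[3] <- "n_patients"
  agg[order(-agg$n_patients, agg$gene5, agg$gene3), , drop = FALSE]
}

#' Distances between intra-chromosomal fusion partners
#'
#' @param fusions data.frame with `chrom5`, `pos5`, `chrom3`, `pos3`; every
#'   row must be intra-chromosomal.
#' @return list with `min`, `max`, and the vector of `distances`
#'   (`abs(pos5 - pos3)` per fusion).
#' @export
partner_distance_stats <- function(fusions) {
  if (any(fusions$chrom5 != fusions$chrom3)) {
    stop("inter-chromosomal record in input")
  }
  d <- abs(fusions$pos5 - fusions$pos3)
  list(min = min(d), max = max(d), distances = d)
}

#' Render a base-pair distance for reporting
#'
#' Megabase distances print with 2 significant figures (`"5.1 Mb"`), kilobase
#' distances to the nearest integer (`"35 kb"`), smaller values in bp.
#'
#' @param bp Distance in bases.
#' @export
format_distance <- function(bp) {
  if (bp >= 1e6) paste0(signif(bp / 1e6, 2), " Mb")
  else if (bp >= 1e3) paste0(round(bp / 1e3), " kb")
  else paste0(bp, " bp")
}

#' Cohort-level fusion summary
#'
#' @param fusions data.frame with `sample`, `gene5`, `gene3`, `chrom5`,
#'   `pos5`, `chrom3`, `pos3`.
#' @param pmap A `PatientMap`; `n_patients` defaults to the number of
#'   distinct patients in the map (pass explicitly to include fusion-free
#'   patients).
#' @param mechanisms Optional character vector of mechanism labels, one per
#'   fusion row.
#' @param structures Optional character vector of structure classes per row.
#' @param subtypes Optional named character vector sample -> subtype label;
#'   missing samples group as `"unlabeled"`.
#' @param cytobands Optional `CytobandTable` for per-band breakpoint density.
#' @param n_patients Optional cohort size for the patient fractions.
#' @return A `CohortSummary` list: `n_patients`, `frac_with_fusion`,
#'   `frac_multiple`, `mechanism_fractions`, `structure_fractions`,
#'   `chrom_breakpoints` (overall), `chrom_by_subtype`, `band_density`.
#' @export
summarize_cohort <- function(fusions, pmap, mechanisms = NULL,
                             structures = NULL, subtypes = NULL,
                             cytobands = NULL, n_patients = NULL) {
  pat <- .patient_of(pmap, fusions$sample)
  all_pat <- unique(unclass(pmap))
  if (is.null(n_patients)) n_patients <- length(all_pat)
  per_pat <- table(factor(pat, levels = unique(pat)))
  frac_with <- length(unique(pat)) / n_patients
  frac_multi <- sum(tapply(seq_along(pat), pat, length) > 1L) / n_patients

  mech_frac <- NULL
  if (!is.null(mechanisms)) {
    classified <- mechanisms[!is.na(mechanisms)]
    mech_frac <- prop.table(table(classified))
  }
  struct_frac <- NULL
  if (!is.null(structures)) {
    struct_frac <- prop.table(table(structures[!is.na(structures)]))
  }

  bp <- data.frame(sample = rep(fusions$sample, 2L),
                   chrom = c(fusions$chrom5, fusions$chrom3),
                   pos = c(fusions$pos5, fusions$pos3))
  chrom_counts <- table(bp$chrom)

  chrom_by_subtype <- NULL
  if (!is.null(subtypes)) {
    st <- subtypes[bp$sample]
    st[is.na(st)] <- "unlabeled"
    chrom_by_subtype <- table(st, bp$chrom)
  }

  band_density <- NULL
  if (!is.null(cytobands)) {
    bands <- vapply(seq_len(nrow(bp)), function(i) {
      tryCatch(band_of(bp$chrom[i], bp$pos[i], cytobands),
               error = function(e) NA_character_)
    }, character(1))
    band_density <- sort(table(bands[!is.na(bands)]), decreasing = TRUE)
  }

  structure(list(n_patients = n_patients,
                 n_fusions = nrow(fusions),
                 n_samples = length(unique(fusions$sample)),
                 frac_with_fusion = frac_with,
                 frac_multiple = frac_multi,
                 mechanism_fractions = mech_frac,
                 structure_fractions = struct_frac,
                 chrom_breakpoints = chrom_counts,
                 chrom_by_subtype = chrom_by_subtype,
                 band_density = band_density),
            class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat("CohortSummary:", x$n_fusions, "fusions,", x$n_samples, "samples,",
      x$n_patients, "patients\n")
  cat(sprintf("  fraction with >=1 fusion: %.3f; with >1 fusion: %.3f\n",
              x$frac_with_fusion, x$frac_multiple))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value conditional on the table margins: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed the observed table's. The odds ratio is
#' the sample odds ratio ad/bc.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return list with `odds_ratio` and `p_value`.
#' @export
association_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("negative counts")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  m <- a + c_          # first-column margin
  n <- b + d
  k <- a + b           # first-row margin
  or <- (a * d) / (b * c_)
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  # relative tolerance guards ties computed in floating point
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p_value = min(p, 1))
}
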