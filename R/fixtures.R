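# ---------------------------------------------------------------------------
# Packaged reference tables: the 13 validated single-end-cohort fusions and
# the recurrent-partner fusion list, as published.
# ---------------------------------------------------------------------------

#' Load the packaged single-end cohort fusion table
#'
#' Thirteen validated fusion transcripts from the 24-sample single-end
#' color-space cohort: partner symbols, junction and wild-type junction read
#' counts, cytoband, strands, 1-based breakpoint coordinates (hg19) and the
#' predicted structure type. `UAR` marks an unannotated-region partner.
#'
#' @return data.frame with one row per fusion.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_ivy_fusions.tsv",
                      package = "fusionscape", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$chrom5 <- df$chrom
  df$chrom3 <- df$chrom
  df
}

#' Load the packaged recurrent-partner fusion list
#'
#' Fusions whose partner genes recur across patients in the combined
#' cohorts: sample id (TCGA aliquot barcode, or the internal cohort id for
#' samples profiled on the single-end platform), partner symbols and
#' 1-based breakpoint coordinates (hg19).
#'
#' @return data.frame with one row per fusion record.
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2_recurrent_fusions.tsv",
                      package = "fusionscape", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Alias table linking internal cohort samples to TCGA participants
#'
#' Three samples of the single-end cohort were also profiled by TCGA; their
#' internal ids resolve to the TCGA participant for patient-level
#' deduplication.
#' @return data.frame with columns `sample`, `patient`.
#' @export
ivy_aliases <- function() {
  data.frame(sample = c("SN214", "SN154", "SN187"),
             patient = c("TCGA-74-6583", "TCGA-74-6573", "TCGA-74-6578"),
             stringsAsFactors = FALSE)
}
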