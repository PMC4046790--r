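# ---------------------------------------------------------------------------
# Segmented copy-number profiles and fusion-mechanism classification.
# Segment coordinates are 1-based inclusive (SEG convention); every segment
# start and end is treated as a genomic breakpoint.
# ---------------------------------------------------------------------------

#' Construct a segment set from a segment table
#'
#' @param segments data.frame with columns `sample`, `chrom`, `start`, `end`
#'   (1-based inclusive), `seg_mean`, optionally `n_markers`. Segments are
#'   sorted per chromosome; overlap within a sample+chromosome is an error.
#' @return A `SegmentSet` (single sample) or a named list of them when the
#'   table holds several samples.
#' @export
segment_set <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("sample", "chrom", "start", "end", "seg_mean") %in% names(segments)))
  if (any(segments$start > segments$end)) stop("segment with start > end")
  samples <- unique(segments$sample)
  build_one <- function(s) {
    df <- segments[segments$sample == s, , drop = FALSE]
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    for (ch in unique(df$chrom)) {
      x <- df[df$chrom == ch, ]
      if (nrow(x) > 1L) {
        ov <- which(x$start[-1] <= x$end[-nrow(x)])
        if (length(ov)) {
          stop("overlapping segments for sample ", s, " on ", ch,
               " (rows ", ov[1], " and ", ov[1] + 1L, " after sorting)")
        }
      }
    }
    rownames(df) <- NULL
    bp <- df[, c("chrom", "start", "end")]
    breakpoints <- rbind(
      data.frame(chrom = bp$chrom, pos = bp$start),
      data.frame(chrom = bp$chrom, pos = bp$end))
    breakpoints <- unique(breakpoints[order(breakpoints$chrom, breakpoints$pos), ])
    rownames(breakpoints) <- NULL
    structure(list(sample = s, segments = df, breakpoints = breakpoints),
              class = "SegmentSet")
  }
  if (length(samples) == 1L) build_one(samples) else
    setNames(lapply(samples, build_one), samples)
}

#' Read a SEG file (TCGA level-3 layout)
#'
#' Six tab-separated columns: sample, chromosome, start, end, marker count,
#' segment mean (log2 ratio); gzip accepted. Unsorted input is sorted
#' silently; overlapping segments are a hard error.
#'
#' @param path File path.
#' @return A `SegmentSet` or named list of them (one per sample).
#' @export
read_segments <- function(path) {
  df <- read.delim(if (grepl("\\.gz$", path)) gzfile(path) else path,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("SEG file needs 6 columns, got ", ncol(df))
  names(df)[1:6] <- c("sample", "chrom", "start", "end", "n_markers", "seg_mean")
  segment_set(df)
}

#' Write a SEG file
#' @param segsets A `SegmentSet` or list of them.
#' @param path Output path.
#' @export
write_segments <- function(segsets, path) {
  if (inherits(segsets, "SegmentSet")) segsets <- list(segsets)
  df <- do.call(rbind, lapply(segsets, function(s) {
    x <- s$segments
    if (is.null(x$n_markers)) x$n_markers <- NA_integer_
    x[, c("sample", "chrom", "start", "end", "n_markers", "seg_mean")]
  }))
  names(df) <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Distance to the nearest genomic breakpoint
#'
#' @param pos 1-based coordinate.
#' @param chrom Chromosome.
#' @param segset A `SegmentSet`.
#' @return Minimum absolute distance in bases to any segment endpoint on
#'   `chrom`; `Inf` when the chromosome has no segments.
#' @export
nearest_breakpoint <- function(pos, chrom, segset) {
  bp <- segset$breakpoints
  bp <- bp$pos[bp$chrom == chrom]
  if (!length(bp)) return(Inf)
  min(abs(bp - pos))
}

.segment_at <- function(segset, chrom, pos) {
  df <- segset$segments
  df[df$chrom == chrom & df$start <= pos & pos <= df$end, , drop = FALSE]
}

# index (row number within the chromosome's sorted segments) or NA
.segment_index_at <- function(segset, chrom, pos) {
  df <- segset$segments[segset$segments$chrom == chrom, , drop = FALSE]
  i <- which(df$start <= pos & pos <= df$end)
  if (length(i)) i[1] else NA_integer_
}

#' Classify the formation mechanism of a fusion from copy-number segments
#'
#' Decision tree over the six mechanism types, evaluated in a fixed order so
#' ambiguous profiles resolve deterministically:
#'
#' 1. Partners on different chromosomes: `interchromosomal` when at least one
#'    fusion point lies within `window` of a breakpoint, else `none`.
#' 2. Both points interior to one common segment (more than `window` from its
#'    ends) with `seg_mean >= amp_log2`: `focal_amplification` — fusion
#'    points within a genomic amplicon.
#' 3. 5' point within `window` of a segment's end and 3' point within
#'    `window` of the same amplified segment's start: `tandem_duplication`
#'    (head-to-tail duplication of the segment).
#' 4. Points within `window` of the start and end of one segment whose mean
#'    is at least `del_delta` below the smaller flanking mean:
#'    `deletion_based` (interstitial deletion bridges the partners).
#' 5. Both points within `window` of breakpoints with more than one whole
#'    segment strictly between the matched breakpoints: `complex`
#'    (chromothripsis-like multi-segment rearrangement).
#' 6. Neither point near any breakpoint, or nothing above applies: `none`.
#'
#' The amplicon checks (2-3) run before the no-breakpoint rule because a
#' fusion interior to an amplicon is, by construction, far from breakpoints.
#'
#' @param fusion A list/row with `chrom5`, `pos5`, `chrom3`, `pos3`
#'   (1-based fusion points), e.g. a `CuratedFusion` row.
#' @param segset The sample's `SegmentSet`.
#' @param window Breakpoint matching window in bases (default 30000, the
#'   marker-resolution scale of SNP-array segmentation).
#' @param amp_log2 Amplification threshold on the segment mean (default 0.9).
#' @param del_delta Required drop below flanking means for the deletion call
#'   (default 0.3).
#' @return A `MechanismCall`: `label`, plus `evidence` (nearest-breakpoint
#'   distance per point, containing-segment means, count of segments strictly
#'   between matched breakpoints).
#' @export
classify_mechanism <- function(fusion, segset, window = 30000,
                               amp_log2 = 0.9, del_delta = 0.3) {
  c5 <- fusion$chrom5; p5 <- fusion$pos5
  c3 <- fusion$chrom3; p3 <- fusion$pos3
  d5 <- nearest_breakpoint(p5, c5, segset)
  d3 <- nearest_breakpoint(p3, c3, segset)
  seg5 <- .segment_at(segset, c5, p5)
  seg3 <- .segment_at(segset, c3, p3)
  ev <- list(dist5 = d5, dist3 = d3,
             mean5 = if (nrow(seg5)) seg5$seg_mean[1] else NA_real_,
             mean3 = if (nrow(seg3)) seg3$seg_mean[1] else NA_real_,
             between = NA_integer_)
  call <- function(label) structure(list(label = label, evidence = ev),
                                    class = "MechanismCall")

  if (c5 != c3) {
    return(call(if (d5 <= window || d3 <= window) "interchromosomal" else "none"))
  }

  segs <- segset$segments[segset$segments$chrom == c5, , drop = FALSE]
  i5 <- .segment_index_at(segset, c5, p5)
  i3 <- .segment_index_at(segset, c3, p3)

  # amplicon membership: both points interior to one common amplified segment
  if (!is.na(i5) && !is.na(i3) && i5 == i3) {
    s <- segs[i5, ]
    interior <- (p5 - s$start) > window && (s$end - p5) > window &&
                (p3 - s$start) > window && (s$end - p3) > window
    if (interior && s$seg_mean >= amp_log2) return(call("focal_amplification"))
  }

  # tandem duplication: 5' point at an amplified segment's 3' end and the
  # 3' point at the same segment's 5' start (head-to-tail duplication)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$seg_mean >= amp_log2 &&
        abs(p5 - s$end) <= window && abs(p3 - s$start) <= window) {
      return(call("tandem_duplication"))
    }
  }

  if (d5 > window && d3 > window) return(call("none"))

  # deletion: points flank one segment relatively deleted vs its neighbors
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    matched <- (abs(p5 - s$start) <= window && abs(p3 - s$end) <= window) ||
               (abs(p5 - s$end) <= window && abs(p3 - s$start) <= window)
    if (!matched) next
    flanks <- c(if (i > 1L) segs$seg_mean[i - 1L],
                if (i < nrow(segs)) segs$seg_mean[i + 1L])
    if (length(flanks) && s$seg_mean <= min(flanks) - del_delta) {
      return(call("deletion_based"))
    }
  }

  # complex: both points at breakpoints with > 1 whole segment between them
  if (d5 <= window && d3 <= window) {
    lo <- min(p5, p3); hi <- max(p5, p3)
    between <- sum(segs$start > lo + window & segs$end < hi - window)
    ev$between <- between
    call2 <- function(label) structure(list(label = label, evidence = ev),
                                       class = "MechanismCall")
    if (between > 1L) return(call2("complex"))
    return(call2("none"))
  }
  call("none")
}

#' @export
print.MechanismCall <- function(x, ...) {
  cat("MechanismCall:", x$label, "\n")
  invisible(x)
}

#' Correlation of copy number at the two fusion points
#'
#' Pearson correlation between the containing-segment means at the 5' and 3'
#' fusion points across fusions; high correlation indicates co-amplification
#' of the joined segments, the pattern seen for complex rearrangements.
#'
#' @param fusions data.frame with `sample`, `chrom5`, `pos5`, `chrom3`,
#'   `pos3`.
#' @param segsets Named list of `SegmentSet`, keyed by sample.
#' @return Pearson correlation coefficient (needs >= 3 covered fusions).
#' @export
partner_copy_correlation <- function(fusions, segsets) {
  pairs <- lapply(seq_len(nrow(fusions)), function(i) {
    f <- fusions[i, ]
    ss <- segsets[[f$sample]]
    if (is.null(ss)) return(NULL)
    s5 <- .segment_at(ss, f$chrom5, f$pos5)
    s3 <- .segment_at(ss, f$chrom3, f$pos3)
    if (!nrow(s5) || !nrow(s3)) return(NULL)
    c(s5$seg_mean[1], s3$seg_mean[1])
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) < 3L) {
    stop("need >= 3 fusions with both points covered by segments")
  }
  cor(pairs[, 1], pairs[, 2])
}
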