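# SOLiD dibase code. Bases map to 2-bit values A=0, C=1, G=2, T=3 and the
# color of a dibase (prev, cur) is the XOR of the two values:
#   identical pair -> 0; {AC,CA,GT,TG} -> 1; {AG,GA,CT,TC} -> 2; {AT,TA,CG,GC} -> 3.
.base_code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
.code_base <- c("A", "C", "G", "T")

.bases_to_int <- function(bases) {
  v <- .base_code[strsplit(toupper(bases), "", fixed = TRUE)[[1]]]
  if (anyNA(v)) {
    stop("cannot encode ambiguous or non-ACGT base in '", bases, "'")
  }
  unname(v)
}

#' Encode a nucleotide sequence to SOLiD color space
#'
#' Each color encodes the transition between two adjacent bases (the first
#' transition pairs the sequencing primer base with the first read base),
#' under the standard SOLiD dibase matrix. A single-base substitution in the
#' underlying DNA changes two adjacent colors, whereas a measurement error
#' changes one color and corrupts all downstream decoded bases.
#'
#' @param primer Single primer base, one of `A`, `C`, `G`, `T`.
#' @param bases Nucleotide string over `A/C/G/T`.
#' @return Color string over `0/1/2/3`, same length as `bases`.
#' @export
#' @examples
#' encode_colors("A", "AAAA")  # "0000"
#' encode_colors("T", "ACGT")  # "3131"
encode_colors <- function(primer, bases) {
  stopifnot(is.character(primer), nchar(primer) == 1L)
  p <- unname(.base_code[toupper(primer)])
  if (is.na(p)) stop("invalid primer base '", primer, "'")
  if (nchar(bases) == 0L) return("")
  b <- .bases_to_int(bases)
  prev <- c(p, b[-length(b)])
  paste(bitwXor(prev, b), collapse = "")
}

#' Decode a SOLiD color string back to nucleotides
#'
#' Inverse of [encode_colors()]: starting from the primer base, each color
#' determines the next base via the dibase matrix.
#'
#' @param primer Single primer base.
#' @param colors Color string over `0/1/2/3`. A missing-color symbol (`.`)
#'   aborts decoding with an error unless `policy = "truncate"`, in which
#'   case the decoded prefix before the first `.` is returned.
#' @param policy Either `"error"` (default) or `"truncate"`.
#' @return Nucleotide string of the decoded bases.
#' @export
#' @examples
#' decode_colors("A", "000")   # "AAA"
#' decode_colors("T", "3131")  # "ACGT"
decode_colors <- function(primer, colors, policy = c("error", "truncate")) {
  policy <- match.arg(policy)
  p <- unname(.base_code[toupper(primer)])
  if (is.na(p)) stop("invalid primer base '", primer, "'")
  if (nchar(colors) == 0L) return("")
  ch <- strsplit(colors, "", fixed = TRUE)[[1]]
  miss <- which(ch == ".")
  if (length(miss)) {
    if (policy == "error") {
      stop("missing color '.' at position ", miss[1], "; cannot decode")
    }
    ch <- ch[seq_len(miss[1] - 1L)]
    if (!length(ch)) return("")
  }
  v <- suppressWarnings(as.integer(ch))
  if (anyNA(v) || any(v < 0L | v > 3L)) stop("invalid color symbol in '", colors, "'")
  out <- integer(length(v))
  cur <- p
  for (i in seq_along(v)) {
    cur <- bitwXor(cur, v[i])
    out[i] <- cur
  }
  paste(.code_base[out + 1L], collapse = "")
}

#' Read a csfasta-style color-space read file
#'
#' Plain-text format: a header line `>id` followed by one sequence line
#' consisting of the primer base then the color string (e.g. `T01230...`).
#' Gzip-compressed files are accepted.
#'
#' @param path File path.
#' @return A data.frame with columns `id`, `primer`, `colors`.
#' @export
read_csfasta <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || sum(hdr) * 2L != length(lines)) {
    stop("malformed csfasta in '", path, "': expected alternating header/sequence lines")
  }
  ids <- sub("^>", "", lines[hdr])
  seqs <- lines[!hdr]
  data.frame(
    id = ids,
    primer = substr(seqs, 1L, 1L),
    colors = substring(seqs, 2L),
    stringsAsFactors = FALSE
  )
}

#' Write reads in csfasta format
#'
#' @param reads data.frame with columns `id`, `primer`, `colors`.
#' @param path Output path.
#' @export
write_csfasta <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", reads$id, "\n", reads$primer, reads$colors), con, sep = "\n")
  invisible(path)
}

#' Extract partially mapped reads at a candidate fusion breakpoint
#'
#' A junction-spanning read maps to the known exon only up to the breakpoint,
#' so its matched length against the exon flank is short of the full read.
#' Reads with fewer than `max_exon_match` matched exon bases (default 35, for
#' 50 bp reads) but at least `min_anchor` matched bases are retained as
#' junction-read candidates.
#'
#' @param reads data.frame of aligned reads carrying at least `matched_length`
#'   (bases matching the exon flank) and `boundary` (the genomic coordinate of
#'   the exon boundary each read is anchored to).
#' @param boundary Genomic coordinate (1-based) of the candidate breakpoint.
#' @param max_exon_match Exclusive upper bound on exon-matched bases.
#' @param min_anchor Minimum exon-matched bases to admit a read.
#' @return The subset of `reads` that are partial at this boundary.
#' @export
extract_partial_reads <- function(reads, boundary, max_exon_match = 35L,
                                  min_anchor = 10L) {
  stopifnot(is.data.frame(reads), "matched_length" %in% names(reads))
  keep <- reads$matched_length < max_exon_match & reads$matched_length >= min_anchor
  if ("boundary" %in% names(reads)) {
    keep <- keep & reads$boundary == boundary
  }
  reads[keep, , drop = FALSE]
}

# Column layout of a junction-anchored read for consensus building:
# bases 1..matched_length lie on the exon side of the junction; column 0 is
# the last exon base, column k > 0 the k-th base of the unmatched tail.
# Color j of a read (j >= 2) reports the transition into base j; the first
# color involves the primer and is never compared across reads.
.read_columns <- function(read) {
  n <- nchar(read$colors)
  cols <- seq_len(n) - read$matched_length  # column of each base
  list(cols = cols, colors = as.integer(strsplit(read$colors, "")[[1]]))
}

.tail_colors <- function(read) {
  # named integer vector: tail column -> color (transition columns >= 1)
  x <- .read_columns(read)
  keep <- x$cols >= 1L & seq_along(x$cols) >= 2L
  stats::setNames(x$colors[keep], x$cols[keep])
}

#' Build consensus sequences from junction-spanning reads
#'
#' Reads anchored at a shared exon boundary are greedily clustered by
#' agreement of their unmatched tails (mismatch fraction over overlapping
#' tail columns at most `max_mismatch_frac`; the longest-tailed read seeds
#' each cluster). Each cluster with at least `min_support` members yields one
#' consensus: every member is decoded from its own primer and each column
#' takes the plurality base over the covering reads. Because a color error
#' corrupts all downstream bases of one read but leaves the other reads'
#' votes intact, column-wise base voting self-corrects isolated color
#' errors. Distinct junction isoforms fall into distinct clusters and yield
#' one consensus each.
#'
#' @param reads data.frame with columns `id`, `primer`, `colors`,
#'   `matched_length` (and optionally `qual`, a comma-separated per-color
#'   quality string used for tie-breaks).
#' @param min_support Minimum reads per consensus (default 2).
#' @param max_mismatch_frac Maximum tail mismatch fraction for cluster
#'   membership (default 0.1).
#' @return A list of consensus objects (class `ConsensusSeq`), each with
#'   `seq` (base space), `colors`, `support` (per-column vote counts),
#'   `members` (read ids), `junction_col` (1-based offset in `seq` of the
#'   last exon-side base), and `cluster`.
#' @export
build_consensus <- function(reads, min_support = 2L, max_mismatch_frac = 0.1) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0L) return(list())
  # deterministic order: longest tail first, then id
  tail_len <- nchar(reads$colors) - reads$matched_length
  ord <- order(-tail_len, reads$id)
  reads <- reads[ord, , drop = FALSE]

  tails <- lapply(seq_len(nrow(reads)), function(i) .tail_colors(reads[i, ]))
  cluster <- integer(nrow(reads))
  seeds <- list()
  for (i in seq_len(nrow(reads))) {
    assigned <- FALSE
    for (ci in seq_along(seeds)) {
      s <- tails[[seeds[[ci]]]]
      t <- tails[[i]]
      shared <- intersect(names(s), names(t))
      if (!length(shared)) next
      mm <- sum(s[shared] != t[shared]) / length(shared)
      if (mm <= max_mismatch_frac) {
        cluster[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      seeds[[length(seeds) + 1L]] <- i
      cluster[i] <- length(seeds)
    }
  }

  out <- list()
  for (ci in seq_along(seeds)) {
    idx <- which(cluster == ci)
    if (length(idx) < min_support) next
    members <- reads[idx, , drop = FALSE]
    cons <- .vote_consensus(members)
    cons$cluster <- length(out) + 1L
    out[[length(out) + 1L]] <- cons
  }
  out
}

# Per-column plurality vote over read-decoded bases. Each member read is
# decoded from its own primer; a color error corrupts only that read's
# downstream bases, and columns covered by several reads outvote it. Ties
# break by highest summed per-color quality, then the alphabetically
# smallest base. The consensus color string is re-derived from the voted
# bases.
.vote_consensus <- function(members) {
  n <- nrow(members)
  basecol <- vector("list", n)
  for (i in seq_len(n)) {
    r <- members[i, ]
    x <- .read_columns(r)
    q <- rep(1L, length(x$colors))
    if (!is.null(members$qual) && !is.na(r$qual) && nzchar(r$qual)) {
      qv <- as.integer(strsplit(r$qual, ",", fixed = TRUE)[[1]])
      if (length(qv) == length(x$colors)) q <- qv
    }
    basecol[[i]] <- data.frame(
      col = x$cols,
      base = strsplit(decode_colors(r$primer, r$colors), "")[[1]],
      q = q)
  }
  bs <- do.call(rbind, basecol)
  cols <- sort(unique(bs$col))
  bases <- character(length(cols))
  support <- integer(length(cols))
  for (k in seq_along(cols)) {
    bt <- bs[bs$col == cols[k], , drop = FALSE]
    support[k] <- nrow(bt)
    agg <- stats::aggregate(cbind(votes = rep(1L, nrow(bt)), q = bt$q) ~ base,
                            data = bt, FUN = sum)
    best <- agg[agg$votes == max(agg$votes), , drop = FALSE]
    if (nrow(best) > 1L) best <- best[best$q == max(best$q), , drop = FALSE]
    bases[k] <- sort(best$base)[1]
  }
  seq <- paste(bases, collapse = "")
  structure(list(
    seq = seq,
    colors = if (nchar(seq) > 1L) substring(encode_colors(bases[1], seq), 2L)
             else "",
    support = support,
    members = sort(members$id),
    junction_col = sum(cols <= 0L)
  ), class = "ConsensusSeq")
}

#' @export
print.ConsensusSeq <- function(x, ...) {
  cat("ConsensusSeq:", nchar(x$seq), "bp,", length(x$members),
      "reads, junction after base", x$junction_col, "\n")
  cat(x$seq, "\n")
  invisible(x)
}
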