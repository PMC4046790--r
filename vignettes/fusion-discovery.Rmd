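---
title: "Discovering and characterizing gene fusions from bulk RNA-seq with fusionscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and characterizing gene fusions with fusionscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionscape)
```

## The problem

Gene fusions — hybrid transcripts joining sequence from two genomic loci —
are among the most actionable genomic lesions in solid tumours, and in
glioblastoma they concentrate in a small number of amplified hotspots
(the EGFR locus at 7p11, the MDM2/CDK4 amplicon at 12q14-15). Most fusion
callers target Illumina paired-end data. `fusionscape` implements a
complete discovery and characterization workflow that also covers the
harder single-end, color-space case: candidate genes are found from
*expression* anomalies rather than from discordant read pairs, and the
junction itself is reconstructed from partially mapped reads.

The package has four layers:

1. **Discovery** (`compute_exon_rpkm()`, `copa_z()`,
   `select_candidate_genes()`, `walk_breakpoints()`,
   `extract_partial_reads()`, `build_consensus()`, `split_align()`),
   chained by `run_discover()`.
2. **Curation** of external caller output (`read_caller_records()`,
   `merge_caller_records()`, `apply_curation()`).
3. **Characterization**: copy-number mechanism (`classify_mechanism()`)
   and chimeric protein structure (`build_chimeric()`,
   `classify_structure()`).
4. **Cohort reporting** (`recurrent_partner_genes()`,
   `summarize_cohort()`, `association_test()`).

A deterministic simulator (`simulate_cohort()`) generates toy cohorts with
planted fusions and is the substrate of the package's end-to-end tests.

## The discovery model

### Exon-level RPKM and the outlier statistic

Expression is quantified per exon as RPKM (reads per kilobase of exon per
million mapped reads): for exon counts $c$, exon length $\ell$ (kb) and
library size $N$ (millions), $x = c / (\ell N)$. A fusion leaves a
distinctive footprint at this resolution: the fused allele is typically
driven by a strong promoter or amplified, so the *retained* exons of each
partner are overexpressed relative to the cohort while the lost exons are
not.

Overexpression in a small subset of samples is exactly what the
cancer-outlier statistic detects. For each exon the samples' RPKM values
are sorted ascending and a trimmed center and spread are computed over the
lowest $k = \lceil f\,n \rceil$ values ($f = 0.75$ by default, standard
deviation with the $n-1$ denominator over those $k$ values); the score of
sample $i$ is

$$z_i = \frac{x_i - \mu_{\text{trim}}}{\sigma_{\text{trim}}}.$$

Trimming the upper tail is the point: an outlier sample inflates its own
$z$ instead of inflating the spread that would hide it. An exon is an
outlier in a sample when $z > 4$ (strict), and only exons reaching RPKM
$> 20$ in at least one sample are eligible — both thresholds are exposed
(`z_min`, `rpkm_min`). A constant exon has no outlier signal; below a
spread floor of $10^{-8}$ all its scores are defined as 0 rather than
diverging. The trim fraction is a parameter (`trim_fraction`) because
reasonable variants of the trimmed estimator exist; $f = 0.75$ excludes a
25% upper tail, comfortably above the fraction of samples any recurrent
fusion reaches in practice.

### Exon walking

For each flagged (gene, sample) pair, the per-exon profile is normalized
by that exon's 70th-percentile RPKM across the cohort
(linear-interpolation percentile; the `quantile` parameter). The
normalized profile of an unaffected gene is flat near 1; a fusion shows a
step. Walking the exons 5′→3′ in transcript rank order, any adjacent pair
with a two-fold drop or rise in normalized value
($r_{j+1} \le r_j/2$ or $r_{j+1} \ge 2 r_j$, inclusive) marks the
boundary as a candidate breakpoint; a drop marks the gene as a candidate
5′ partner, a rise as a 3′ partner. Exons silent across the whole cohort
would make the denominator zero; they borrow the gene's smallest positive
denominator, and a gene silent everywhere is skipped.

### Color-space reads and junction consensus

SOLiD instruments report dibase *colors*, each encoding the transition
between adjacent bases (`encode_colors()` / `decode_colors()` implement
the standard matrix: identical pair → 0; AC/CA/GT/TG → 1; AG/GA/CT/TC → 2;
AT/TA/CG/GC → 3, with a known primer base anchoring decoding). Two
properties matter here: decoding requires chaining from an anchor, and a
single color error flips every decoded base downstream of it.

Reads spanning a fusion junction align to the known exon only up to the
breakpoint. `extract_partial_reads()` keeps reads whose exon-matched
length is below 35 bases (for 50 bp reads) but at least `min_anchor = 10`
— the lower bound suppresses spurious 1-2 bp anchors the original rule
leaves unconstrained. The retained reads are clustered greedily by
agreement of their unmatched tails (mismatch fraction ≤ 0.1 over
overlapping tail columns, longest tail seeding each cluster), so distinct
junction isoforms separate into distinct clusters; each cluster with ≥ 2
members yields one consensus.

Consensus calling decodes every member read from its own primer and takes
a per-column plurality vote over bases, with ties broken by summed
per-color quality and then alphabetically. We deliberately vote on
*decoded bases* rather than on colors: a chained decode of column-voted
colors lets one wrongly voted color — possible wherever a column is
covered by a single read — corrupt the entire downstream consensus,
whereas with base voting an error in one read corrupts only that read's
own downstream votes, which multi-read columns outvote. With 30× junction
coverage and a 1% per-color error rate this self-correction is the
difference between recovering all planted junctions and losing some to
failed exon-identity checks.

### Split alignment

`split_align()` maps a consensus as two parts. The exon side must match
the anchor exon flank at ≥ 95% identity. The remainder is aligned
genome-wide by exact 16-mer seeding with ungapped extension (match +1,
mismatch −2) — deterministic and entirely adequate at the scale of a
desk-size genome, which is the regime all packaged analyses run in. The
distal locus is accepted only when its score exceeds the runner-up by
`min_margin = 8` (our quantitative reading of "uniquely mapped", exposed
as a parameter), when it lies outside the anchor gene, and when both
parts are at least `min_part_len = 20` bases — the same anchor length the
paired-end caller configuration uses. Breakpoints are reported 1-based:
the last exon-side base and the first distal base in fusion-transcript
orientation. The 3′ partner is classed `annotated_coding`,
`annotated_noncoding`, or `UAR` (unannotated region) by overlap with the
gene models.

## Curating external caller output

For cohorts processed with paired-end callers, the package reads the
callers' native report layouts (including the unfiltered candidate list,
whose records carry a `candidate_only` flag until reconciled against the
final report) and applies a six-rule filter; every record receives a full
audit trail, one logical column per rule:

1. at least one breakpoint at a known exon boundary (tolerance
   `boundary_tol`);
2. junction-spanning reads vs wild-type exon-exon spanning reads ratio
   strictly > 2 for at least one partner — a wild-type count of 0 passes
   (the ratio is unbounded there, and validated fusions with silent
   wild-type junctions exist);
3. spanning reads ≥ 100 *or* partner outlier z ≥ 5;
4. candidate-only records additionally need partner z ≥ 10;
5. 5′→3′ transcript orientation consistent with the partner strands;
6. the pair absent from a normal-tissue blacklist (default: TFG→GPR128).

Fusions of immediate genomic neighbors are additionally discarded —
read-through transcription mimics them. "Adjacent" is defined as no third
annotated gene lying strictly within the gap between the two spans, with
no distance cutoff, since any fixed distance would be arbitrary. The
partner outlier z of a record is the maximum z over all exons of both
partner genes in that sample: the permissive reading, consistent with
using the score as a discovery gate rather than a penalty.

## Copy-number mechanism classification

Segmented SNP-array profiles (SEG layout) supply genomic breakpoints:
every segment start and end is one. `classify_mechanism()` assigns each
fusion one of six labels, evaluated in a fixed order so ambiguous
profiles resolve deterministically: interchromosomal (different
chromosomes, ≥ 1 point near a breakpoint), focal amplification (both
points interior to one amplified segment), tandem duplication (points
matching the start and end of one amplified segment head-to-tail),
deletion-based (points flanking a segment at least `del_delta` below its
neighbors), complex (both points at breakpoints with more than one whole
segment strictly between), or none. The amplicon checks run before the
no-breakpoint rule because a fusion interior to an amplicon is, by
construction, far from any breakpoint; testing "no nearby breakpoint"
first would make focal amplification unreachable.

Three parameters control matching, none of which has a canonical
published value: `window = 30000` bases (the marker-resolution scale of
SNP-array segmentation), `amp_log2 = 0.9` (≈ high-level gain on a log2
ratio scale), and `del_delta = 0.3`. All are exposed and reported with the
output. `partner_copy_correlation()` quantifies co-amplification of the
joined segments as the Pearson correlation of segment means at the two
fusion points.

## Chimeric structure prediction

`build_chimeric()` concatenates the 5′ gene's exons through the
breakpoint (the 5′ breakpoint must be an exon boundary in transcript
orientation) with the partner transcript from its breakpoint exon onward,
or with `uar_extension = 10` kb of genomic sequence for an unannotated
partner — long enough that a stop codon or polyadenylation-like end is
always encountered in practice. When a gene has several transcript
models, the longest coding transcript represents it (ties to the lowest
identifier).

`classify_structure()` assigns one of eight classes by where the junction
falls relative to both coding regions. The reading-frame test is
arithmetic: translation enters the 3′ sequence at phase
$c_5 \bmod 3$ (5′ coding bases retained) and is in frame iff that matches
the 3′ entry point's phase within its own CDS, with no intervening stop —
`in_frame` requires the predicted peptide to actually cross the junction,
since a hybrid junction codon can itself be a stop. Out-of-frame
junctions truncate the 5′ protein. Junctions upstream of the 5′ CDS yield
promoter swaps (`promoter_swap_full` when the 3′ CDS survives intact,
`promoter_swap_n_truncated` otherwise); a noncoding 3′ partner yields
`noncoding_truncation`; an unannotated partner yields `truncated_gene`
inside the CDS and `extended_3utr` after it; a noncoding 5′ partner
yields `no_protein` (a peptide is only reported if an open reading frame
of ≥ 50 codons exists, and the class does not change — the transcript is
not under coding selection either way). Peptides are translated from the
5′ start codon to the first stop. `kinase_domain_retained()` then checks
whether the peptide contains, unbroken, the full image of an annotated
kinase-domain interval of either partner; domain intervals are user
input in protein coordinates, keeping the package free of any homology
search dependency.

## Cohort reporting

Recurrence is counted per *patient*, not per sample: TCGA barcodes
collapse at the participant field (`TCGA-XX-NNNN`), so portion and
aliquot suffixes never double-count, and an alias table maps
internal cohort ids onto TCGA participants where both cohorts profiled
the same patient. The `UAR` placeholder is never counted as a gene.
`summarize_cohort()` reports patient fractions with ≥ 1 and > 1 fusion,
mechanism and structure-class distributions, per-chromosome breakpoint
histograms (optionally per subtype label; unlabeled samples group as
`"unlabeled"`) and a per-cytoband breakpoint density — the tabular
equivalent of a fusion-hotspot ring plot. `association_test()` implements
the two-sided exact test on a 2×2 table from its conditional
hypergeometric definition (summing the probabilities of all tables, given
the margins, no more probable than the observed one, with a
$1 + 10^{-7}$ relative tie tolerance against floating-point equality),
and the sample odds ratio $ad/bc$.

## The simulator

`simulate_cohort()` builds a toy reference — by default three 400 kb
chromosomes carrying 24 multi-exon genes (three noncoding per chromosome)
with engineered CDSs (start in exon 2, stop in the second-to-last exon,
no premature stops) and an annotation-free tail ≥ 20 kb per chromosome as
unannotated-region substrate — and plants one fusion per affected sample,
covering all eight structure classes and all six mechanisms. The planted
conditions follow the study design the package targets: a 24-sample
cohort, 50 bp single-end color-space reads, 30× junction depth, 8-fold
outlier overexpression of the fused alleles, wild-type junction coverage
near 3×, and log-normal background noise with $\sigma_{\log} = 0.2$ —
a noise level at which an 8-fold outlier sits far above the z = 4
threshold, as real driver fusions do, without making the threshold
vacuous. Copy-number profiles are constructed so each mechanism's
defining geometry holds exactly (e.g. the tandem-duplication segment's
endpoints coincide with the fusion points). Everything is a pure function
of the seed, byte for byte.

What the simulator does *not* emulate bounds what the green tests show:
uniform-random genome (no repeats or paralogy, so split-alignment
uniqueness is easier than on a real genome), no subclonal mixtures, no
position- or sequence-dependent error profile, no library-preparation
biases, and decoy caller records that violate exactly one curation rule
each (real false positives violate several at once or none cleanly).
Passing the round trip demonstrates internal correctness of the chain,
not sensitivity on real tumours.

Problem sizes in the packaged tests and acceptance script were chosen to
keep a full run in minutes on one core: 1.2 Mb of genome, 24 genes, 24
samples, 8 planted fusions, ~30 junction reads each; the codec is checked
exhaustively over all primer × sequence combinations up to length 8, and
the curation filter against an independently coded rule evaluator on
1000 randomized records.

## A worked example

```{r example, eval = FALSE}
library(fusionscape)

sim <- simulate_cohort(sim_config(seed = 1))
res <- run_discover(sim$reference$genome, sim$reference$annotation,
                    sim$data$matrix, sim$data$reads)
res$candidates[, c("sample", "gene5", "pos5", "gene3", "pos3",
                   "partner_class", "junction_reads")]

# mechanism and structure for each planted fusion
tr <- sim$planted$truth
classify_mechanism(tr[1, ], sim$planted$segsets[[tr$sample[1]]])
classify_structure(build_chimeric(tr[1, ], sim$reference$annotation,
                                  sim$reference$genome))

# published-cohort reproductions
t2 <- load_table2()
pmap <- build_patient_map(t2$sample, aliases = ivy_aliases())
head(recurrent_partner_genes(t2, pmap))
```

## Known limitations

* The split aligner is ungapped and exact-seeded: junctions inside
  repeats, or distal segments with indels near the breakpoint, are
  rejected as non-unique or low-identity rather than rescued.
* Discovery pursues expression *drops* as 5′ anchors; a fusion whose 5′
  partner shows no drop (e.g. both partners equally expressed cohort-wide)
  is only reachable through the external-caller curation path.
* Frame prediction ignores stop-codon readthrough and selenocysteine
  recoding, and structure classes are called on one representative
  transcript per gene.
* The exact-test implementation enumerates the hypergeometric support; it
  is intended for the small 2×2 tables of cohort association testing, not
  for large-count contingency problems.
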