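# fusionscape

Gene-fusion discovery and characterization for bulk tumour RNA-seq, with
copy-number integration. The package targets the workflow used for
glioblastoma cohorts, where fusions concentrate in amplified hotspots
(the EGFR locus at 7p11, the MDM2/CDK4 amplicon at 12q14-15): it
discovers fusions from *expression* anomalies in single-end 50 bp SOLiD
color-space data, curates candidate fusions reported by external
paired-end callers, classifies how each fusion formed from segmented
copy-number profiles, predicts the chimeric protein, and summarizes
recurrence across a cohort. It is written for computational biologists
analyzing tumour RNA-seq cohorts, and ships a deterministic
synthetic-cohort simulator used to validate every stage end to end.

## The method

**Discovery (single-end color-space data).** Expression is quantified as
exon-level RPKM, `x = count / (exon_kb × library_millions)`. For each
exon, a trimmed outlier score is computed over the cohort: with RPKM
values sorted ascending and `k = ⌈0.75·n⌉`, the trimmed mean μ and
standard deviation σ are taken over the lowest `k` values and each sample
scores `z = (x − μ)/σ`; trimming the upper tail lets an outlier sample
inflate its own score instead of the spread that would hide it. Exons
with RPKM > 20 somewhere and z > 4 flag a (gene, sample) pair. The gene's
per-exon profile, normalized by each exon's cohort-wide 70th-percentile
RPKM, is then walked 5′→3′: a two-fold drop or rise between adjacent
exons marks a candidate breakpoint. Reads partially mapped at that
boundary (< 35 of 50 bases matching the exon) are clustered and voted
into consensus sequences — reads are decoded from the SOLiD dibase color
code, in which each symbol encodes a two-base transition and one color
error flips all downstream bases, which is why voting happens per column
on decoded bases. Each consensus is split-aligned: the exon side must
match the anchor flank at ≥ 95% identity, and the remainder is placed
genome-wide by exact 16-mer seeding and ungapped extension, accepted only
if uniquely best by a score margin. The 3′ partner is an annotated coding
gene, a noncoding gene, or unannotated sequence ("UAR").

**Curation (external caller output).** Records from paired-end caller
reports are retained only if they pass six rules (breakpoint at a known
exon boundary; junction/wild-type read ratio > 2 with wild-type 0
passing; ≥ 100 spanning reads or partner outlier z ≥ 5; z ≥ 10 for
records present only in the unfiltered candidate list; 5′→3′ orientation
consistency; not on a normal-tissue blacklist) plus a discard of
adjacent-gene fusions. Every input record gets a per-rule audit trail.

**Mechanism.** Treating every copy-number segment endpoint as a genomic
breakpoint, each fusion is labelled `none`, `focal_amplification`,
`tandem_duplication`, `deletion_based`, `complex`, or
`interchromosomal` from the geometry of its two fusion points against
the sample's segments (matching window 30 kb, amplification threshold
0.9 log2, deletion depth 0.3 log2 below flanks — all configurable).

**Structure.** The chimeric transcript is assembled from the retained 5′
exons plus the 3′ contribution; reading-frame arithmetic at the junction
(retained 5′ coding bases mod 3 vs the 3′ entry phase) and stop-codon
scanning classify it as in-frame, out-of-frame, promoter swap (full or
N-truncated), noncoding truncation, truncated gene, extended 3′ UTR, or
no protein product; kinase-domain retention is tested by exact
containment of the domain's peptide image.

## Worked example

A simulated 24-sample cohort with eight planted fusions, run through the
discovery chain:

```r
library(fusionscape)
sim <- simulate_cohort(sim_config(seed = 1))
res <- run_discover(sim$reference$genome, sim$reference$annotation,
                    sim$data$matrix, sim$data$reads)
res$candidates[, c("sample", "gene5", "pos5", "gene3", "pos3",
                   "partner_class", "junction_reads")]
#>  sample gene5   pos5 gene3   pos3       partner_class junction_reads
#>     S01  G001  50907  G003 106394    annotated_coding             26
#>     S04  G002  80393  G010  74074    annotated_coding             26
#>     S07  G004 132182   UAR 282673                 UAR             36
#>     S02  G009  54480  G013 140721    annotated_coding             22
#>     S05  G011 100485  G014 165756 annotated_noncoding             35
#>     S08  G015 187059   UAR 261864                 UAR             18
#>     S06  G018  80120   UAR 284470                 UAR             22
#>     S03  G019 109686  G017  55920    annotated_coding             22
```

Every row is a recovered junction: the sample, the 5′ anchor gene and its
breakpoint (1-based), the 3′ partner locus and its class, and the number
of reads in the junction consensus. All eight planted junctions are
recovered at their exact coordinates and there are no false calls.
Characterizing the first fusion:

```r
tr <- sim$planted$truth
classify_mechanism(tr[1, ], sim$planted$segsets[[tr$sample[1]]])
#> MechanismCall: focal_amplification
classify_structure(build_chimeric(tr[1, ], sim$reference$annotation,
                                  sim$reference$genome))
#> StructureCall: in_frame - peptide 259 aa
```

The fusion sits inside an amplified segment and fuses the partners in
frame, yielding a 259-residue chimeric protein — matching what the
simulator planted.

Cohort-level recurrence on the packaged published fusion list, counted
per patient (TCGA aliquot barcodes collapse to the participant, and the
alias table maps internal cohort ids onto TCGA participants):

```r
t2 <- load_table2()
pmap <- build_patient_map(t2$sample, aliases = ivy_aliases())
head(recurrent_partner_genes(t2, pmap))
#>            gene n_patients
#> 1          EGFR          9
#> 2        LANCL2          6
#> 3 RP11-745C15.2          5
#> 4         NFASC          4
#> 5        SEPT14          4
#> 6         FGFR3          3
```

EGFR partners in fusions of nine distinct patients — the dominant
recurrent partner — followed by its 7p11 neighbours LANCL2, the noncoding
RNA RP11-745C15.2 and SEPT14. Partner distances on the validated
single-end cohort fusions range from 35 kb to 5.1 Mb
(`partner_distance_stats(load_table1())`).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/fusionscape-cli.R` (subcommands `simulate`, `discover`,
`report`).

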