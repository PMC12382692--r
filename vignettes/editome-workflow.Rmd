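---
title: "Calling, testing and integrating an RNA editome"
author: "editomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling, testing and integrating an RNA editome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editomics)
```

## The problem

Bulk RNA-seq of two phenotype groups — here modelled on an intestinal
histology contrast, a high-villus-height (HVH) and a low-villus-height (LVH)
group of four biological replicates each — supports two parallel analyses:
which genes are differentially *expressed*, and which genes are
differentially *edited* at the RNA level. RNA editing (A-to-I deamination by
ADAR enzymes, read as G by the sequencer; C-to-U deamination by APOBEC
enzymes, read as T) leaves single-nucleotide signatures in aligned reads
that look like variants against the genomic reference. `editomics`
implements the downstream half of such a study: it consumes per-sample
variant records (VCF), a reference genome (FASTA), gene models (GTF/GFF3),
an expression count matrix and a phenotype table, and produces retained
editing sites, gene-level editing quantification, differential calls for
both omics tracks, gene-set enrichment, and a joint nine-quadrant
classification with phenotype correlation. Everything upstream — trimming,
alignment, variant calling — is out of scope; the package starts at
annotated variant records.

Because the interesting guarantees are statistical, the package also ships
a first-class synthetic-study generator with planted ground truth, so every
stage can be tested end to end without any external data.

## Site calling

### The hard-filter battery

Candidate records are triaged with seven site-level criteria. A record
fails when any of the following holds:

| criterion | fails when |
|---|---|
| QD (quality by depth) | < 2.0 |
| FS (Fisher strand bias, phred) | > 60.0 |
| MQRankSum | < −12.5 |
| ReadPosRankSum | < −8.0 |
| MQ (RMS mapping quality) | < 40.0 |
| SOR (symmetric odds ratio) | > 3.0 |
| depth deviation | any sample's depth < 1/3× or > 3× the site's cross-sample mean |

All comparisons are strict, so a record sitting exactly on a boundary
passes. The depth-deviation criterion deserves a note: the underlying idea
is that a real editing site should have broadly comparable coverage across
individuals, and a sample whose depth deviates from the site mean by more
than threefold in either direction marks the site as unreliable. We apply
it per sample against the cross-sample mean depth at the site; it can be
switched off (`depth_deviation = FALSE`). Records with a missing quality
annotation fail closed with reason `missing:<field>` by default
(`missing = "pass"` inverts this). `hard_filter()` always reports the full
list of violated criteria, not just the first, so filter attribution is
auditable.

### Retention of sample calls

The editing frequency of a sample call is the edited-read (alt) count over
the total depth at the site; it is undefined at zero depth. A sample call
is retained iff mean alt base quality ≥ 25, depth ≥ 5, alt depth ≥ 3 and
frequency in [0.10, 1.00] — all boundaries inclusive. A *site* is retained
when at least one sample call survives (configurable via `min_samples`);
the same per-group rule defines group presence for the shared/exclusive
site overlap. Both thresholds compose monotonically: relaxing any one of
them can only grow the retained set, a property the test suite checks.

### Classification and annotation

Each retained site records its literal base change and an editing class.
Two modes are provided because the strand bookkeeping of published class
tables is not always internally consistent:

* `"collapsed"` (default): A>G and T>C are A-to-I; C>T and G>A are C-to-U.
  This mapping is invariant under strand complementation, so a minus-strand
  gene classifies identically whether read in reference or gene
  orientation.
* `"literal"`: A>G *or T>A* count as A-to-I, C>T or G>A as C-to-U, reading
  one published pairing verbatim. T>A is not the complement partner of
  A>G, so this mode is not strand-symmetric; it exists to reproduce that
  tabulation, not because we recommend it.

Sites in genes are classified in gene-strand orientation; intergenic sites
are classified literally and flagged `strand_unresolved`.

Genomic region is assigned by precedence: splicing (within 2 bp of an
exon–intron boundary, intron side) > CDS exon > 5'UTR > 3'UTR > intron
(`ncRNA_intronic` when the host gene is non-coding) > upstream >
downstream > intergenic, with upstream/downstream meaning a strand-aware
1 kb window (configurable). Exons of non-coding genes count as exonic.
When two genes could claim a site at equal precedence, the
lexicographically smaller gene id wins — a documented, deterministic
tie-break that matters only for overlapping annotation.

Coding effects substitute the edited base into its codon (strand-aware),
translate with the standard genetic code and call synonymous /
nonsynonymous / stopgain / stoploss. The canonical example is the
APOBEC-style C-to-U edit turning CAA into a premature UAA stop.

## Gene-level quantification and testing

Edited reads are aggregated per gene by plain summation over the gene's
retained sites, each site weighted equally — the gene-level "editing
level" is a count, which is what makes count-based testing applicable to
the editome track. TPM is computed against the exon-union length per gene
and column-normalizes to one million.

Both tracks are tested with the same negative-binomial Wald workflow:

1. **Normalization** — median-of-ratios size factors (the median, per
   sample, of count ratios to each gene's geometric mean across samples,
   computed over genes with no zero counts), rescaled to geometric mean 1.
2. **Dispersion** — per-gene method-of-moments on normalized counts,
   `alpha = max((v − m)/m², 1e-8)` with `v` the pooled within-group
   variance, shrunk toward a fitted mean–dispersion trend
   `alpha(m) = a0 + a1/m` with weight 0.65. At four replicates per group
   the gene-wise moment estimate is extremely noisy — without shrinkage
   many genes land on the floor by chance and the test becomes
   anticonservative, while full trend substitution overshoots the other
   way because the moment estimator is slightly biased upward. The default
   weight was chosen by checking the null rejection rate across a range of
   true dispersions (NB size 8–50) and sits close to the nominal 5% across
   that range.
3. **Wald test** — per-gene NB GLM `mu = s_j · q · 2^(beta · x_j)` fit at
   the fixed dispersion (log link, log size factors as offset);
   `z = beta / SE(beta)` with the SE taken from the NB Fisher information
   (the GLM's ancillary dispersion is pinned at 1 — the NB variance is
   already fully specified by the dispersion, and letting the summary
   estimate a Pearson factor on top would make the statistic ignore it);
   two-sided p from the standard normal.

Fold changes are oriented LVH vs HVH: positive means higher in LVH. Calls
use the per-track conventions: differentially edited genes (REGs) at
|log2FC| **>** 1, differentially expressed genes (DEGs) at |log2FC| **≥**
1, both at raw p < 0.05. No multiple-testing correction enters the calls —
the thresholds are deliberately the raw-p conventions of the study design
this package models — but a Benjamini–Hochberg column is emitted for
users who want it. Exact numerical agreement with DESeq2 is a non-goal
(no Cox–Reid adjustment, no LFC shrinkage); the test suite instead checks
distributional behaviour (type-I error within [0.035, 0.065] under the
null at n = 4 per group) and cross-checks fold changes against DESeq2 on a
shared dataset (correlation > 0.98).

```{r difftest-demo}
cfg <- sim_config(n_genes = 60, seed = 1)
g <- simulate_genome(cfg)
ed <- simulate_editing(cfg, g)
es <- call_editing_sites(ed$variants, g$models, g$genome)
gem <- aggregate_gene_editing(es, g$models)
reg <- diff_test(gem, ed$groups[colnames(gem)], track = "editing")
attr(reg, "counts")
```

## Enrichment

Over-representation uses the one-sided hypergeometric test of the overlap
between a hit list and each gene set, both intersected with the tested
universe. Preranked GSEA sorts genes by log2 fold change and walks the
ranking: the running sum rises by `|score|^p / N_R` at set members
(default weight p = 1) and falls by `1/(N − k)` at non-members; the
enrichment score is the maximum deviation from zero. Significance comes
from gene-label permutations (random same-size sets), because the input is
a preranked list rather than per-sample profiles. The permutation p-value
is sign-matched — a positive ES is compared against the positive tail of
the permutation null and mirrored for negative — with the +1 small-sample
correction, so p ≥ 1/(n_perm + 1) and null p-values are uniform (a
property the suite verifies with a KS check). Defaults: 1000 permutations,
minimum set size 5.

## Integration

The nine-quadrant classification trichotomizes each track's log2 fold
change at |lfc| ≥ t (default t = 1, boundary inclusive): down, unchanged,
up. The numeric quadrant indices are cosmetic — the categorical label is
canonical — and the default lookup anchors (edit_up, expr_down) at 1, the
double-ns centre at 5, and (edit_down, expr_up), i.e. high expression with
low editing, at 9. Corner quadrants 1, 3, 7, 9, where both tracks change,
are flagged high-confidence. Negating both axes reflects every gene
through the centre (quadrant q maps to 10 − q), and genes tested in only
one track are excluded from the table but reported alongside, never
silently dropped.

Phenotype statistics use Welch's t-test by default — at four replicates
per group the equal-variance assumption buys little and costs robustness —
with the pooled-variance Student test available via `var_equal = TRUE`.
Gene–phenotype association uses the Pearson correlation with the exact
t-transform p-value on n − 2 degrees of freedom.

## The synthetic study

`sim_config()` fixes the study conditions; `run_study()` executes the full
chain on them. The generator emulates:

* a random genome with non-overlapping genes on both strands, each with
  one transcript, one or two introns, and (for coding genes) an in-frame
  CDS flanked by UTRs; about 10% of genes are non-coding;
* editing sites placed mostly inside gene bodies with negative-binomial
  depths (mean 50, size 20) and binomially sampled edited reads at a
  per-site baseline frequency drawn uniformly from 0.1–0.3;
* 20 REG genes whose frequency gains +0.6 in the HVH group — at the
  baseline this gives a true gene-level |log2FC| near 2 in edited-read
  counts;
* ~85% of sites constructed as strand-consistent A-to-I or C-to-U
  changes, the rest as other substitutions;
* site-level quality annotations drawn from clearly passing ranges, with
  a configurable fraction of decoys each violating exactly one criterion
  (so filter attribution is testable), the depth-deviation decoy planted
  as one sample at ten times the mean depth;
* expression counts at NB mean 300 and size 25 (biological CV 0.2, the
  standard rule-of-thumb for genetically identical model organisms, which
  matches the genetically uniform, uniformly housed cohort this design
  models), with 20 DEG genes at log2FC +2 in LVH and 10 genes planted in
  both panels;
* phenotypes at the group means 379.3 µm (HVH) and 290.7 µm (LVH) villus
  height, SD 25 µm, with crypt depths analogous; negative normal draws are
  resampled.

A single master seed drives deterministic per-stage child seeds, so a
config reproduces its study byte for byte, including all written files.

What the generator does **not** emulate: read-level errors, alignment and
mapping artifacts, repeat/Alu context, hyper-editing clusters, isoform
complexity, library-composition biases, or known-SNP contamination. A
passing test suite therefore demonstrates that the statistics do what they
claim on data satisfying the model's assumptions — it does not certify
performance on real alignments, where upstream artifacts dominate and the
hard-filter battery carries the load it was designed for.

## Numerical choices and limitations

* Dispersion floor 1e-8; all-zero genes are reported `NA` and excluded.
* Editing frequency is undefined at zero depth; such sample calls are
  simply not retained.
* PCA imputes missing frequencies as 0, centres sites, and fixes component
  signs by making the largest-magnitude loading positive.
* The ES tie-break follows the running walk: candidates are evaluated in
  walk order and the earliest extremum wins.
* Quadrant thresholds are boundary-inclusive (|lfc| = t counts as
  changed); the REG/DEG call thresholds follow their per-track strict/
  inclusive conventions.
* Problem sizes used by the test suite and the acceptance script — studies
  of 40–500 genes and null panels of 1000 genes — were chosen as the
  smallest sizes at which the distributional contracts (type-I error,
  recovery rates, null uniformity) are stable.
* Known limitations: the Wald test at n = 4 leans on the dispersion trend
  and the normal reference, so p-values are approximate in the extreme
  tails; raw p thresholds control nothing family-wise; the generator's
  one-transcript genes sidestep isoform ambiguity that real annotation
  carries (the GTF reader accepts multi-isoform input and unions exons
  per gene); scaling one sample's counts leaves size factors exactly
  proportional but perturbs per-gene estimates through that sample's
  sampling noise — the estimates are close, not bit-identical.
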