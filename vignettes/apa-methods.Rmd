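---
title: "Methods: poly(A) tag analysis of alternative polyadenylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A) tag analysis of alternative polyadenylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In plants, most genes carry more than one functional cleavage and
polyadenylation site. Which site is used decides the 3′ UTR content of the
transcript — and with it stability, translatability and localization — and
site choice shifts under stress. 3′-end tag sequencing (PAT-seq and
kindred protocols) reads one tag per polyadenylation event, anchored at
the poly(A) junction, so each mapped tag marks one cleavage position at
single-nucleotide resolution. `patapa` turns per-sample sets of such tags
into poly(A) clusters (PACs), differential-usage statistics, 3′ UTR length
dynamics, and alternative-polyadenylation (APA) event calls for a
two-condition (control `CK` vs treatment `ST`), replicated design.

This vignette documents the model and every numerical choice a maintainer
or reviewer might question. All empirical statements here are the ones the
test suite and `scripts/acceptance.R` compute; none are quoted from
elsewhere.

## From tags to poly(A) clusters

**Cleavage coordinate.** The cleavage position of a tag is the 3′-most
*aligned* base in transcriptional orientation: the reference-space
alignment end on `+`, the alignment start on `-`. Soft-clipped bases are
excluded — in a 3′-end protocol the clipped tail is oligo(dT) or adaptor,
not genomic evidence. All internal coordinates are 0-based half-open;
conversions happen only at the file boundaries (GFF3 and SAM are 1-based,
BED and bedGraph 0-based), which removes the usual off-by-one churn.

**Internal-priming filter.** Oligo(dT) primers anneal to genomic A-rich
tracts as readily as to poly(A) tails, creating false cleavage signals. A
tag is discarded when the `ip_window` = 10 nt of genomic sequence
immediately downstream of its cleavage position (sense strand) contains
≥ `ip_max_a` = 7 adenosines, or starts with a run of ≥ `ip_run_a` = 6
consecutive adenosines. This two-branch heuristic is the field's standard
shape for the filter; all three numbers are exposed because published
criteria vary. Under a uniform base composition the false-removal
probability of a genuine tag is about 0.4% (the binomial tail of 7-of-10
plus the leading-run term), which the simulator's no-tract configuration
confirms empirically (< 1% of tags removed).

**Clustering.** Tags within `cluster_window` = 24 nt are merged by
single-linkage over sorted positions: a new PAC starts whenever the gap to
the previous tag exceeds the window. The rule is deterministic,
order-invariant, and equivalent to connected components of the pairwise
within-24-nt linkage graph (the test suite proves the equivalence against
an independent transitive-closure oracle on random instances). Each PAC's
*summit* — the modal tag position, ties broken toward the distal
(downstream) side — represents the site. Distal tie-breaking is the
conservative choice for 3′ UTR lengthening calls and is configurable in
spirit: it is isolated in one small function.

**Assignment.** PACs are assigned by summit, not span, because a cluster
span can straddle an annotation boundary while the summit is the single
best estimate of the cleavage site. Candidate regions per gene are the
annotated 3′ UTR, CDS, introns, 5′ UTR, and a downstream *extension*:
200 nt past the annotated 3′ UTR end, or 200 + 218 nt past the gene end
when no 3′ UTR is annotated (218 nt standing in for a typical average 3′
UTR length in crucifers). The extension rescues genuine sites that fall
past conservative gene models; setting it to zero demotes those PACs to
intergenic, which the tests exercise. A summit hitting exactly one
(gene, region) pair takes that assignment; hits in several regions or
genes are `AMB` (ambiguous), resolved to the gene with a 3′ UTR hit when
one exists; no hit is `INTERGENIC`. Reports pool `EXTENDED_UTR3` with
`UTR3`. PACs with fewer than `min_pats` = 10 tags summed over *all*
samples are dropped; the pooled (rather than per-sample) reading of the
support filter is a deliberate choice, exposed as a parameter, since
either convention is defensible.

When several transcripts exist, the representative transcript is the one
with the longest annotated 3′ UTR, falling back to the longest transcript;
this maximizes the surface on which 3′ UTR dynamics can be computed.
`min_mapq` defaults to 10 and is configurable; tag inputs may also be
pre-extracted BED6 cleavage sites, in which case no quality field exists.

## Differential expression of PACs and genes

Counts are normalized by median-of-ratios: sample `j`'s size factor is the
median over units of `count[i,j] / geomean_i`, computed over units
positive in every sample (with a positive-subset fallback for sparse
matrices). Gene expression is the sum of PAT counts over the gene's PACs
(ambiguous PACs count for their resolved gene; intergenic PACs are
excluded), so the same test applies at both levels.

The test itself is a moderated negative-binomial Wald test. Per unit, a
pooled method-of-moments dispersion is estimated from the within-condition
means and variances of normalized counts, then shrunk toward the trimmed
across-unit mean with `prior_df` = 10 prior degrees of freedom; the Wald
statistic for log2 fold change ≠ 0 is referred to a t distribution with
residual-plus-prior degrees of freedom. The moderation step is essential
at three replicates per condition: a per-unit plug-in dispersion with a
normal reference is badly anticonservative (the estimator has ~4 degrees
of freedom), while a t(4) reference is calibrated but loses most of its
power at Benjamini–Hochberg-adjusted thresholds. Sharing dispersion
information across units — the same move DESeq2, edgeR and limma make —
restores both properties at once; the acceptance script verifies type-I
error in [0.03, 0.07] at p < 0.05 under the null and ≥ 0.8 power for
4-fold changes at mean 100, dispersion 0.1, n = 3 + 3. Units whose
moderated dispersion hits the 1e-8 floor are Poisson-like and switch to an
exact conditional binomial test of the ST count sum given the total. No
fold-change shrinkage, dispersion trend fitting, or independent filtering
is performed: numerical parity with DESeq2 is explicitly a non-goal, and
the simplified test is documented as such. Significance is `padj < 0.05`
(BH) throughout.

## 3′ UTR length dynamics

For genes with at least two PACs in the 3′ UTR (annotated or extension),
the per-PAC 3′ UTR length is the distance from the stop-codon-adjacent 3′
UTR start to the PAC summit, and the gene's *weighted 3′ UTR length* in a
condition is the usage-share-weighted mean of those lengths. Two
statistics summarize change between conditions:

* **Direction, `r`** — per sample, the weighted length is computed from
  that sample's counts; `r` is the Pearson correlation across samples
  between the condition indicator (CK = 0, ST = 1) and the per-sample
  weighted length, so `r > 0` means lengthening under ST. The
  length-measurement and direction conventions are this package's
  operationalization (the literature describes the quantities without
  formulas); both are isolated behind `weighted_utr_length()` and
  `direction_statistic()` so alternatives can be swapped in. Zero-variance
  cases return `r = 0` with a flag.
* **Significance** — a classical Pearson chi-square on the 2 × k table of
  pooled per-condition PAC totals, BH-adjusted across all eligible genes.
  When any expected cell is below 5 the asymptotic p value is replaced by
  a Monte-Carlo one (2000 table permutations, driven by the run seed).
  Genes whose PAC sets differ between conditions keep the union of PACs
  with zeros where absent, keeping the table well-formed; PACs with zero
  totals in both conditions are dropped.

A gene is classified `LENGTHEN` iff `r > 0` and `chi2_padj < 0.05`,
`SHORTEN` iff `r < 0` and `chi2_padj < 0.05`, else `UNCHANGED`. Joining
with the gene-level fold change yields the lengthen-and-up /
lengthen-and-down quadrant counts.

**Known limitation.** The chi-square treats pooled condition totals as
multinomial draws; replicate-level NB noise inflates the statistic by
roughly `1 + dispersion × mean` per cell. At the replicate
reproducibility typical of 3′-tag counting (dispersion on the order of
0.01) and BH adjustment this stays manageable — the null-safety run below
measures the realized false-call rate — but on noisier designs the test
will over-call, and a replicate-aware usage test would be the principled
upgrade.

## APA event calls

* **Switching** — a gene with at least one significantly upregulated and
  one significantly downregulated PAC (PAC-level `padj < 0.05`, opposite
  signs). Note that a strong usage shift also produces this pattern: a
  true lengthening gene with a large distal shift genuinely contains one
  up- and one down-regulated PAC, so switching and lengthening are
  overlapping, not exclusive, descriptions.
* **Condition-specific PACs** — zero raw counts in *every* replicate of
  the other condition and a raw total ≥ `min_total` = 10 in the named
  condition. The strict-zero rule takes "only expressed under ST"
  literally; `max_other` relaxes it for noisier data.
* **Condition-inducible APA** — ≤ 1 expressed PAC under CK and ≥ 2 under
  ST, with "expressed" meaning a nonzero raw condition total ≥
  `min_total`. The floor mirrors the PAC support filter because no
  separate convention suggests itself.
* **Homolog overlap** — cross-species comparison consumes a user-supplied
  many-to-many id map; ortholog inference is out of scope, so homology is
  data, not computation.

## The synthetic experiment generator

`simulate_apa_experiment()` builds a toy genome of regularly spaced gene
loci (5′ UTR 100 nt, two CDS exons of 300 nt around a 150 nt intron, 3′
UTR 350 nt, generous flanks), a GFF3 annotation, per-sample BED tag files,
and full ground truth. Its defaults *are* the study conditions for the
acceptance runs and are not tuned per run:

* 1000 genes, 50% with 2–5 sites (weights 0.55/0.25/0.15/0.05 over
  2/3/4/5);
* per-gene per-sample mean tag count log-normal around 100 (sdlog 0.5),
  emulating a deeply sequenced library's expression spread;
* NB dispersion 0.01 (~10% CV), the replicate reproducibility one expects
  from tag counting of pooled seedlings grown in controlled chambers —
  tag assays avoid the gene-length and fragmentation variance of standard
  RNA-seq;
* three replicates per condition;
* planted events: 10% lengthening and 2% shortening (distal/proximal
  usage shift of 0.2), 3% switching, 3% ST-specific, 1.6% ST-inducible;
* Gaussian tag jitter with sd 5 nt around each true site — comfortably
  inside the 24 nt cluster window, so one site yields one cluster; true
  sites are spaced ≥ 100 nt apart so neighboring clusters cannot chain
  together through stray jittered tags;
* 10% of genes carry a planted genomic A-tract emitting internal-priming
  artifact tags. Artifact tags sit exactly at the tract's 5′ edge, with no
  jitter: the mispriming position is fixed by where the primer anneals,
  unlike true cleavage, which wobbles;
* 10% of genes lack a 3′ UTR annotation, exercising the 218 nt fallback
  extension.

Event classes are architecturally separated so that ground truth is
unambiguous: switching genes switch between a CDS PAC and a 3′ UTR PAC;
specific and inducible genes carry one constitutive 3′ UTR PAC plus
ST-only PACs in the CDS or intron. These genes therefore have fewer than
two 3′ UTR PACs and stay out of the UTR-dynamics eligible set, and each
planted mechanism maps to exactly one caller. Because an inducible gene's
ST-only PACs are genuinely condition-specific as well, specific-call
false positives are scored against *all* planted ST-only sites, and
switching false positives only against genes with identical planted
per-PAC means in both conditions.

What the generator does **not** emulate: sequencing error and alignment
artifacts (input is post-alignment by design), microheterogeneity of
cleavage beyond Gaussian jitter, poly(A)-signal sequence context,
overlapping gene models, multi-species genomes (cross-species comparisons
are two independent runs plus a constructed homolog map), and any
correlation structure between replicates. Passing the recovery tests
therefore demonstrates the pipeline's internal correctness under its own
model, not performance on real libraries.

## Problem sizes and numerical choices

The acceptance runs use the generator's default 1000-gene experiment
(~600k tags) and 2000-unit count simulations; the module tests use smaller
instances (tens of genes, hundreds of clustering positions), sizes chosen
to keep each statistical check's Monte-Carlo error well inside its
decision margin. Other numerical details, in one place: dispersion
estimates are floored at 1e-8 after moderation; the log2 fold change uses
a 0.5 pseudocount on normalized condition means; degenerate direction
statistics return 0 with a flag rather than NA to keep joins total;
Monte-Carlo chi-square p values cannot fall below 1/(B+1) ≈ 5e-4, so
low-count genes cannot reach BH significance — a deliberate conservatism;
the bedGraph writer emits per-base intervals without merging equal-valued
neighbors, keeping the export a plain histogram; clustering ids and all
output tables are sorted, so identical seeds reproduce every output file
byte for byte.
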