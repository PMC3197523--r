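---
title: "Probe-coherence screening and differential expression for single-suture craniosynostosis arrays"
author: "sutureGIC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-coherence screening and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sutureGIC)
```

## The problem

Whole-transcript expression arrays interrogate each gene with a probe set of
many oligonucleotide probes. When a gene's transcript truly varies across a
sample population, its probes move together; when a probe set mostly
measures hybridization noise, the probes wander independently. In a
case-control study of single-suture craniosynostosis — premature fusion of
the sagittal, coronal or metopic suture, with calvarial osteoblast lines
from cases and controls profiled on arrays — this distinction is the first
analysis decision: of roughly thirty thousand genes, which ones carry
population-level signal worth testing at all?

`sutureGIC` implements that screen and everything downstream of it:

1. **Normalization**: quantile normalization across arrays, then
   median-polish summarization of each probe set (the two in-scope steps of
   the classic RMA chain; inputs are assumed background-handled and on the
   log2 scale already).
2. **GIC screening**: a per-gene *Gene Information Content* score with a
   permutation-derived cutoff, then a top-*K* ranking.
3. **Differential expression**: per-gene linear models with age and sex
   adjustment and processing-batch blocking, empirical-Bayes moderated
   t-tests, Benjamini-Hochberg adjustment, and percent-change effect sizes.
4. **Set logic**: the significant-and-large filter and the seven-region
   Venn partition across the three case-vs-control contrasts.
5. **Clustering** of the selected genes x samples matrix, and **gene-set
   over-representation** against GMT collections.
6. A **synthetic probe-level generator** that emulates the study design, so
   every stage is testable without any array download.

## The GIC statistic

For one gene, collect its probe-level values into the $p \times n$ block
$X$ (probes by samples), subtract each probe's mean across samples, and
take the singular value decomposition of the centered block. The score is

$$\mathrm{GIC} = \frac{s_1^2}{\sum_i s_i^2},$$

the fraction of probe-level variance explained by the first singular value.
The first right-singular vector is the gene's *eigengene* — the dominant
shared expression pattern — and the GIC is the share of probe variance that
pattern carries. A perfectly coherent probe set is rank one and scores 1; a
block of independent noise spreads its spectrum and scores near
$1/\min(p, n-1)$, so the null level depends on probe-set size.

Numerical conventions, chosen where the procedure is otherwise
underdetermined:

* **Centering** is per probe (row), before the SVD. Without it, probe
  affinity offsets dominate $s_1$ and every gene looks coherent;
  "variance explained" is only meaningful on centered data. We take the
  statistic on the quantile-normalized, pre-summarization probe matrix.
* **Single-probe genes** score 1.0 by construction; they are flagged and
  excluded from top-*K* selection by default, because a coherence claim
  about one probe is vacuous. Zero-variance blocks score 0.0 and are
  flagged degenerate.
* The implementation computes each block's score from the eigenvalues of
  the $p \times p$ Gram matrix $X_cX_c^\top$ (equal to the squared singular
  values), which keeps the permutation loop fast with hundreds of samples;
  the test suite checks this path against a plain SVD and against an
  independent eigendecomposition written in test code.

### The permutation cutoff

How much GIC is "beyond chance" given the platform's probe-set size
profile? The null is built by shuffling the probe-to-gene map uniformly at
random — each permuted gene receives the same *number* of probes as a real
gene, but a random selection of them — and recomputing every permuted
gene's score. Scores from all permutations are pooled and the cutoff is the
99th percentile (linear interpolation between order statistics, the same
quantile rule used everywhere). 1000 permutations is the conventional
count; genes at or below the cutoff are removed and the top 2000 by GIC
(ties broken by gene id, for determinism) form the screened list.

Two deliberate choices here: the permutation preserves the probe-set size
multiset, because GIC depends on block size and a size-ignorant null would
be miscalibrated; and all permuted scores are pooled into one null giving a
single cutoff value, rather than per-size nulls — a single threshold is
what the downstream filter consumes, and size-stratified variants can be
built from the returned pooled scores if wanted.

## Normalization choices

Quantile normalization forces every array to the reference distribution
(the row-wise mean of sorted columns); ties receive the mean of the
reference values at their rank positions, making the transform
deterministic and idempotent. Median polish fits
$\mathrm{value} = \mathrm{overall} + \mathrm{probe} + \mathrm{sample}$
by alternating row and column medians — rows first, midpoint medians for
even counts, relative tolerance $10^{-6}$ on the sum of absolute residuals,
at most 20 sweeps — and reports overall + sample effects as the gene's
expression. The row-first order and tie rule are fixed so reruns are
byte-identical. Background correction of raw intensities is out of scope:
all inputs are taken as log2 values, since every downstream computation
depends only on the normalized scale.

`summarizeProbeSubset()` applies the same polish to a chosen subset of a
gene's probes. That is the cross-hybridization check: when a pseudogene
shares sequence with a real gene's 3' end, the 3'-probe summary shows
differential expression that the 5'-probe summary does not, revealing that
the probe set is reporting its homolog.

## The differential-expression model

Per gene, expression is modeled on group means (control, sagittal, coronal,
metopic), age in months as a linear term, and sex (female = 0, male = 1):
units follow the demographic table of the emulated design. The microarray
processing date (batch) is handled as a random effect in the
`duplicateCorrelation` style: a consensus intra-batch correlation is pooled
across genes, then each gene is fit by generalized least squares with that
correlation. A `batch = "fixed"` mode fits batch indicator columns instead;
on balanced designs the two agree closely (tested), and the fixed mode is
the fallback when batches are few or confounded. Full per-gene REML with
several variance components is a non-goal.

Moderated t-statistics follow the standard empirical-Bayes squeeze: a
scaled inverse-chi-square prior $(d_0, s_0^2)$ fit to the gene-wise
variances by moment matching on $\log s^2$, posterior variance
$(d_0 s_0^2 + d s^2)/(d_0 + d)$, and $d + d_0$ degrees of freedom. The fit
is delegated to `limma`, which is also what the moderated pipeline in this
field runs in production; the prior-recovery behaviour is tested against
variances simulated from known hyperparameters.

Contrasts cover the three case-vs-control comparisons, the three direct
case-vs-case comparisons, and a pooled all-cases-vs-control contrast. The
pooled contrast is defined as the sample-size-weighted average of the three
case-group means minus the control mean — i.e. it treats the 199 cases as
one group while still borrowing the covariate adjustment of the four-group
model.

Effect sizes are reported as log2 fold change and as signed percent
change, $\mathrm{sign}(\beta)\,(2^{|\beta|} - 1) \cdot 100$, rounded half
away from zero for display. The signed form keeps down-regulation
symmetric: a halving is $-100\%$, so magnitudes beyond 100 occur in both
directions.

**Thresholds.** The screening filter flags genes that are *significant*
(raw moderated p strictly below 0.05) and *large* (absolute percent change
strictly above 50). The significance threshold is applied to **raw**
p-values, not BH-adjusted ones: a screen that keeps roughly a third of the
list is only consistent with the raw-p reading, and the BH-adjusted values
are carried in every table for users who want FDR semantics instead. Both
thresholds and the choice of column are configurable.

**Venn regions.** Flagged sets of the three case-vs-control contrasts are
partitioned into regions m1–m7: m1 = all three; m2 = coronal & metopic
only; m3 = coronal & sagittal only; m4 = metopic & sagittal only; m5/m6/m7
= unique to coronal/metopic/sagittal. The m3/m4 assignment follows
contrast-name order after m2 is pinned to the coronal-metopic pair, which
is the pairing of scientific interest (those two groups travel together).

## Clustering and enrichment

Heatmap orderings use agglomerative clustering with 1 − Pearson correlation
distance and average linkage on z-scored gene rows — the standard choice
for expression heatmaps; Euclidean distance and complete/Ward linkage are
available. Because `hclust` leaf order is an implementation accident, the
package applies its own deterministic rule to the merge tree (smaller
subtree first, ties by smallest member id), so reruns and platforms agree.
Zero-variance items are undefined under correlation distance and are
dropped with a warning.

Over-representation of a query list against a GMT collection uses the
one-sided Fisher exact test, computed as the hypergeometric upper tail on
(overlap, query, set, universe), with BH adjustment across sets. The
`"ease"` mode removes one gene from the overlap cell first — the
conservative convention of the DAVID-style annotation tools — and is never
smaller than the Fisher p. The default universe is the full platform gene
list, overridable; the conventional reporting threshold is p < 0.01.

## What the generator emulates — and what it does not

`studyDesign()` defaults are the emulated study's conditions: 50 controls
and 100/50/49 sagittal/coronal/metopic cases, ages drawn uniform-integer
within each group's demographic range (controls 1–120 months, cases much
narrower), and each group's observed male fraction. Ages are drawn from
the ranges rather than forced to match the group means, because the ranges
are hard constraints and the means then emerge. The batch count is not
reported for the real study; the default is 5 processing batches assigned
round-robin, a realistic cadence for ~250 arrays.

Each gene couples a latent gene-level signal to its probes:

$$z_{gs} = \mu_g + \beta_{g,\mathrm{group}(s)} + \beta_{age}\,\mathrm{age}_s
 + \beta_{sex}\,\mathrm{male}_s + b_{g,\mathrm{batch}(s)}
 + \sqrt{c_g}\,\sigma_g u_{gs},$$
$$y_{ps} = a_p z_{gs} + \sqrt{1 - c_g}\,\sigma_g\,\epsilon_{ps},$$

with probe affinities $a_p \sim N(1, 0.2^2)$ fixed per gene, per-batch
offsets $b \sim N(0, 0.3^2)$, and $u, \epsilon$ standard normal. The
coherence $c_g$ splits each probe's stochastic variance between the shared
signal and probe-private noise, so it is what the GIC screen estimates —
while planted fold changes enter the mean structure *unscaled* and are
recoverable without attenuation at any coherence. (Scaling the whole
latent value by $\sqrt{c}$ instead would shrink every planted effect by
the same factor and make effect-size recovery depend on a nuisance
parameter; the split used here keeps the two planted quantities
orthogonal.) Multiplicative affinities make probes differ in gain, which
is what median polish must absorb; setting `affinity_sd = 0` gives the
exact noiseless limits used in unit tests.

Default magnitudes: $\beta_{age} = 0.002$ log2/month and
$\beta_{sex} = 0.1$ log2 — detectable confounders that do not dominate a
0.5 log2 noise scale; probe counts uniform on 4–26, plausible for a
whole-transcript array; baselines uniform on 4–12 log2 units, the usual
occupied range of array summaries. All are arguments.

The generator does **not** simulate raw feature-level intensities, optical
background, spatial artifacts, probe GC effects, or cross-hybridization
(the chimeric-gene test builds that construction explicitly). Passing
tests therefore demonstrate correctness of the statistical machinery under
the assumed additive log-scale model, not robustness to vendor-level
artifacts — on real arrays the upstream background and QC steps this
package declares out of scope still matter.

## Problem sizes used by the test suite

The shipped checks run the machinery at reduced but honest scales, chosen
as the package's own verification budget: the GIC-vs-oracle comparison
uses 1000 random blocks; null calibration of the permutation cutoff uses
20 replicates of 1000 i.i.d.-noise genes x 100 samples with 200
permutations each (the observed pass rate must sit at 1% ± 0.5%);
fold-change recovery plants 0.89, 1.17 and −1.04 log2 units at 50-vs-50
samples and requires the 20-replicate mean within ±0.1; type-I calibration
uses 20 null replicates of 2000 genes at the full 249-sample design (raw
p < 0.05 at 5% ± 1%, BH-positive rate under 2%).

## Known limitations

* The batch random effect assumes one consensus intra-batch correlation
  across genes; strongly gene-specific batch structure is better served by
  the fixed mode or by upstream batch correction.
* The permutation null assumes exchangeability of probes across genes
  after quantile normalization; systematic probe-class effects (e.g. GC
  content) would make the null optimistic.
* GIC favours genes whose variation is shared across probes regardless of
  its source; a strong batch effect common to all probes of a gene raises
  its GIC. Screening before batch-aware modeling is therefore a filter,
  not an inference.
* Single-probe genes cannot be screened meaningfully and are excluded by
  default rather than granted their nominal score of 1.

## A short run

```{r example, eval = FALSE}
design <- studyDesign(seed = 1)
genes  <- c(plantedGenes(400, coherence = 0.3, seed = 1),
            lapply(1:20, function(i)
              plantedGene(sprintf("hit%02d", i), 8, coherence = 0.9,
                          lfc = c(coronal = 1.2, metopic = 1.1))))
pe  <- simulateStudy(design, genes)
ge  <- medianPolishSummarize(quantileNormalize(pe))
gic <- gicAnalysis(quantileNormalize(pe), nPermutations = 1000, seed = 1)
top <- rankAndSelect(gic, 100)
de  <- runDE(ge)
fl  <- flagGenes(de[c("coronal_control", "metopic_control",
                      "sagittal_control")])
vennPartition(fl$coronal_control, fl$metopic_control, fl$sagittal_control)
```

`runPipeline()` wraps the same sequence with tab-delimited/JSON artifacts
and a hashed manifest; see `?runPipeline`.
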