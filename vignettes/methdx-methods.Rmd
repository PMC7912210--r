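---
title: "Region-aware methylome-transcriptome biomarker discovery with methdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-aware methylome-transcriptome biomarker discovery with methdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdx)
```

# The analysis

methdx implements an integrated case/control methylome-transcriptome
analysis for blood-biomarker discovery. Its inputs are an
already-normalized log2 expression matrix (genes x samples), an Illumina
450K-style beta-value matrix (CpG probes x samples), a probe annotation
mapping each CpG to a gene and one of six gene regions (TSS1500, TSS200,
5'UTR, 1stExon, gene body, 3'UTR; probes outside genes are labelled
intergenic), and a sample sheet with case/control labels. Raw-array
preprocessing (background correction, normalization, batch removal) is
deliberately upstream of the package: the contract starts at normalized
matrices.

The pipeline has five statistical stages.

**Beta values and aggregation.** A CpG's methylation level is
$\beta = M/(M + U + a)$, with methylated and unmethylated intensities
$M, U \ge 0$ and offset $a = 100$ stabilising the ratio at low intensity
and keeping $\beta \in [0, 1)$. Region-level methylation of a gene is the
unweighted mean beta of its CpGs in that region; gene-level methylation is
the mean over all the gene's CpGs regardless of region. A (gene, region)
pair without CpGs is absent from the result, never imputed as zero, and a
CpG annotated to several genes contributes to each.

**Differential expression.** Every gene gets the two-group linear model
case vs control with empirical-Bayes variance moderation: the posterior
variance is $s^2_{post} = (d_0 s_0^2 + d s^2)/(d_0 + d)$, where $s^2$ is
the pooled within-group variance on $d$ residual df and the prior
$(d_0, s_0^2)$ is estimated from the ensemble of per-gene variances by the
method of moments under the scaled-F model
$s^2 \sim s_0^2 F(d, d_0)$. The moderated t is referred to $d + d_0$ df.
With moderation disabled ($d_0 = 0$) the statistic is exactly the ordinary
pooled-variance two-sample t, which is how the implementation is
oracle-tested. P-values are two-sided and Benjamini-Hochberg adjusted; a
gene is called differentially expressed iff adjusted p < 0.05 **and**
|log2 fold-change| > 0.2, both inequalities strict. Reference
empirical-Bayes implementations estimate the prior by likelihood on the
log scale instead; the tests demand close (not bit-identical) agreement of
the resulting statistics.

**Differential methylation by the pooled decile rule.** The per-gene
delta-beta (case minus control, so hypo-methylation in cases is negative)
is pooled with the delta-beta of every intergenic CpG, and the 0.1/0.9
empirical quantiles of that pooled vector become the hypo/hyper
thresholds. Using a relative, cohort-internal threshold makes the rule
robust to global methylation shifts (for example cell-composition
differences), which an absolute cut-off is not. A gene is called
hypo-methylated iff its delta-beta lies strictly below the lower decile
**and** the BH-adjusted p from an ordinary equal-variance two-group linear
model on gene-level beta is below 0.05; hyper-methylation mirrors this at
the upper decile. The quantile definition is linear interpolation between
order statistics (R type 7); this choice is documented because no standard
fixes it.

**Dominant regions.** For each differentially methylated gene the
dominant region set contains the region with the most extreme delta-beta
in the gene's direction (most negative for hypo, most positive for hyper)
plus every region whose delta-beta lies strictly within 0.005 beta units
of that extreme — so a gene can have several dominant regions. "Most
extreme in the gene's direction" resolves an ambiguity in the literal
phrase "smallest delta beta", which is ill-defined for hyper-methylated
genes; `extreme = "signed-min"` reproduces the literal reading. Exact ties
at the extreme are broken by the fixed region order TSS1500, TSS200,
5'UTR, 1stExon, Body, 3'UTR.

**Integration and classification.** Up-regulated genes intersected with
hypo-methylated genes give the hypo-up set; hyper-down, hyper-up and
hypo-down are analogous. Under the expected negative coupling of promoter
methylation and expression, hypo-up and hyper-down genes are the biomarker
candidates. Three random-forest classifier views are built on those genes:
log2 expression, gene-level beta over all regions, and beta over the
dominant regions only. Features are ranked by forest importance (mean
decrease in impurity by default, permutation importance optionally),
min-max scaled to [0, 100] for reporting (top feature 100.00, bottom
0.00), and added one by one in rank order; each top-k model is scored by
leave-one-out cross-validation, every left-out sample receiving a case
probability from a model that never saw it. AUC is the Mann-Whitney
statistic with ties counted one half (identical to trapezoidal integration
of the empirical ROC), and its p-value against AUC = 0.5 comes from the
two-sided normal-approximated rank-sum test. The best k is the smallest k
attaining the maximal AUC.

A deliberate fidelity choice: by default the importance ranking is
computed once on the full data set and leave-one-out applies only to AUC
estimation. This replicates the published protocol but leaks ranking
information into the folds, so the per-k AUC curve is optimistically
biased. `incremental_selection(..., nested = TRUE)` re-ranks inside every
training fold and gives the unbiased protocol; the default is fidelity,
the flag is rigour.

# Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `alpha_de`, `alpha_dm` | 0.05 | probability | BH-adjusted p cut-offs (strict) |
| `lfc` | 0.2 | log2 units | absolute fold-change gate (strict) |
| `deciles` | 0.1, 0.9 | probability | pooled delta-beta quantiles |
| `tol` | 0.005 | beta units | dominance tolerance (strict) |
| `a` | 100 | intensity | beta-value stabilising offset |
| `n_trees` | 500 | trees | forest size |
| `mtry` | floor(sqrt(G)) | features | features tried per split |

Forest hyperparameters follow the cited implementation's conventions; all
are exposed because none is dictated by the method itself.

# The synthetic cohort generator

Because the pipeline's reference cohorts cannot be shipped, every stage is
validated against simulated studies with known planted truth
(`simulate_cohort()`). The generator emulates: two groups of 150 cases and
75 controls sharing one sample set (a `split_cohorts` flag regenerates
disjoint expression samples to mimic two-cohort designs); 200 genes with
roughly 12 CpGs each spread over the six regions plus 500 intergenic CpGs;
bimodal 450K-style baseline betas (low and high methylation modes from two
Beta distributions); and planted signal with negative
methylation-expression coupling — 10% of genes hypo-up (beta shift
-0.2 in one or two randomly chosen regions, log2 fold-change +1.0) and 10%
hyper-down (mirrored signs). Planting the methylation effect in only 1-2
regions, rather than uniformly, is what makes dominant-region detection a
meaningful recovery task; probes in affected regions start from mid-range
baselines so the shift cannot be clipped away. All betas are clipped into
[0, 1 - 1e-6] after noise addition because beta is a fraction and
downstream means must stay in range.

The beta noise model stacks four components chosen for realism: probe-level
technical noise (SD 0.04), a subject-level per-(gene, sample) component
(SD 0.02), a per-sample global offset shared by every probe of a sample
(SD 0.04, emulating cell-composition variation — and the reason the decile
rule's cohort-relative thresholds are the right calling strategy), and a
subject-level *penetrance*: only 70% of cases carry the planted
methylation shift, shared across all of a subject's affected genes.
Penetrance is what separates group-level from individual-level signal. A
group-mean effect large enough to clear the decile-plus-BH gate at
n = 225 would otherwise let a forest built on ~30 informative genes
separate the classes perfectly, and every classifier view would saturate
at AUC 1.0; with penetrance $\pi$ the methylation views face a Bayes
ceiling of $1 - (1 - \pi)/2 = 0.85$ while the fully penetrant expression
effects remain separable. That reproduces, as a structural property of
the data rather than a tuned number, the empirically familiar ordering in
which an expression classifier outperforms methylation classifiers and
the dominant-region view is at least as good as the all-region view.

What the generator does **not** emulate: batch effects, age/sex
covariates, probe cross-reactivity, spatial correlation along the genome,
and raw-intensity (IDAT/CEL) artefacts. Passing tests therefore
demonstrate correct recovery of planted signal under this noise model,
not robustness to everything real cohorts contain.

Expected generator-recovery behaviour at the default conditions (fixed
seed, asserted by the test suite): DEG sensitivity >= 0.9, DMG sensitivity
>= 0.7, dominant-region recovery >= 0.8 among genes planted in exactly one
region, leave-one-out AUC of the expression view strictly above both
methylation views, and permuted-label AUC centred on 0.5.

# Numerical choices and degenerate inputs

* Strict inequalities everywhere a threshold is stated (DEG gate, decile
  rule, dominance tolerance); boundary cases are excluded by design and
  tested with binary-representable values.
* All-equal delta-beta collapses both deciles onto the same value and the
  strict rule then calls nothing — the degenerate case degrades to silence,
  not to noise.
* Zero-variance genes with a zero group difference get p = 1; a gene set
  whose variance is zero everywhere raises a typed degenerate-variance
  error rather than producing NaN statistics.
* The moments prior estimator falls back to an infinitely informative
  prior (complete shrinkage to the pooled variance) when the observed
  spread of per-gene variances is at or below what sampling alone implies.
* Min-max importance scaling clamps against floating-point spill just
  outside [0, 100]; an all-equal importance vector returns zeros with a
  warning rather than dividing by zero.
* Missing expression values drop the gene with a warning; probes annotated
  but absent from the beta matrix are skipped with a warning; a gene with
  no CpGs in its dominant set is dropped from that classifier view with a
  warning.
* Every artifact written by `run_pipeline()` carries a metadata header
  (package version, seed, configuration hash) and is checksummed in a
  manifest so tampering is detectable (`verify_manifest()`).

# Problem sizes

The shipped tests and the acceptance script run the full study at 150/75
samples, 200 genes and 500 intergenic CpGs; classifier evaluation uses
500-tree forests under full leave-one-out (225 fits per view). Unit tests
exercise the same code paths at toy sizes (tens of samples, tens of
genes, 50-200 trees) where the asserted quantities are exact oracles
rather than stochastic recoveries.

# Known limitations

* Single-factor designs only: no covariates, pairing or batch terms.
* Gene-level methylation p-values are computed on beta values directly;
  M-value analysis is out of scope.
* The decile thresholds are cohort-relative by construction, so calls are
  not comparable across cohorts with different pooled distributions.
* The default feature-selection protocol inherits the full-data ranking
  leak described above; use `nested = TRUE` for honest per-k curves.
* The shipped 46 + 71 gene signature is a fixture of published symbols
  (with documented canonicalisation of mangled tokens such as SEPT4 and
  dash/dot variants); it carries no expression or methylation data.
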