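---
title: "Measuring X chromosome dosage compensation with xdosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring X chromosome dosage compensation with xdosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdosage)
library(dplyr)
```

## The scientific question

In therian mammals, females silence one X chromosome (X inactivation, XCI),
leaving both sexes with one active X against two copies of every autosome.
Ohno's hypothesis holds that transcription from the single active X is
upregulated to keep X-linked gene dosage in balance with the diploid
autosomes. The standard way to interrogate this is the X:A ratio — the mean
expression of X-linked genes relative to the mean expression of autosomal
genes — in species such as sheep, with 26 autosome pairs plus X.

`xdosage` works on its log2 scale:

* **RXE** (relative X expression): `RXE = log2(x) − log2(a)`, where `x` is
  the mean TPM over X-linked genes and `a` the mean TPM over autosomal genes
  in a sample. `RXE ≥ 0` indicates complete upregulation of the active X,
  `−1 < RXE < 0` partial upregulation, and `RXE ≤ −1` none (the single X
  transcribing at its per-copy rate or less).
* **RGE** (relative gene expression of autosome *i*):
  `RGE_i = log2(a_i) − log2(a_{n−i})`, the mean expression of autosome *i*
  against all other autosomes (never including X, Y or the mitochondrion on
  either side). The spread of RGE values defines the "normal band" of
  chromosome-level expression within which an RXE is judged.

Both statistics are computed on TPM (transcripts per kilobase million),
because TPM normalizes for gene length before sequencing depth and therefore
supports mean comparisons across gene sets of different length composition.

## Gene subgroups

Whether X upregulation looks complete depends heavily on which genes enter
the means, so four subgroups are first-class:

| subgroup | definition | default |
|---|---|---|
| `ALL` | every annotated gene, including silent ones | |
| `EXPRESSED` | TPM ≥ threshold in the sample at hand | threshold 1 TPM, inclusive |
| `XCI_SUBJECT` | `EXPRESSED` minus pseudoautosomal (PAR) genes | |
| `DOSAGE_SENSITIVE` | TPM ≥ threshold in *every* sample of the matrix | |

PAR genes sit in the X/Y-homologous region, escape XCI, and are expressed
from both sex chromosomes; removing them isolates the genes actually subject
to inactivation. Non-PAR escapees are *not* removed — catalogues of
escape genes are unavailable for most livestock genomes, so any such
filter would be arbitrary. `EXPRESSED` membership is evaluated per sample
(the least-assuming reading: a gene can be expressed in kidney but not
lung), while `DOSAGE_SENSITIVE` is a property of the whole matrix
("expressed in all samples"), which is why the latter set is constant across
columns.

A deliberate design choice is **log-of-means**, not mean-of-logs: RXE is the
difference of log2-transformed gene-set *means*, matching the arithmetic
X:A ratio definition. The geometric-mean variant (`method = "mean_of_log"`,
computed over positive TPM only) is exposed for sensitivity analyses because
parts of the dosage-compensation literature use it; the two can differ
materially when expression is skewed, which is itself informative.

Per-sample RXE values are averaged *after* computation
(`tissue_mean_rxe()`), never by pooling replicates into one mean first;
replicate-level values are what the group tests below consume.

## The synthetic-data generator

Every stage is testable without external downloads because the package
ships a generator whose defaults emulate a sheep-like study design:

* 26 autosomes carrying 19,291 genes with a decreasing size gradient, plus
  1,228 X-linked genes of which 20 are PAR (20,519 genes in total);
* tissues brain/kidney/lung, each sampled from control (n = 7), overfed
  (n = 4) and restricted (n = 4) pregnancies, with mixed fetal sexes;
* log-normal per-gene baseline rates (log2 mean 3, log2 SD 1.5 — a heavy
  right tail typical of bulk RNA-seq TPM) and per-sample log-normal noise
  (log2 SD 0.25, chosen for test power rather than fitted to any tissue:
  no dispersion estimates exist for this design);
* a fraction (0.3) of genes silenced to zero, emulating non-expressed genes;
* eight planted X-linked diet-responsive genes with |log2 effect| between
  3.2 and 4.6 split across the overfed and restricted groups (top
  diet-responsive X genes in such designs show > 3 log2-fold changes).

The expression model is multiplicative rather than count-based: the
analysis consumes TPM and all its statistics are functions of TPM means, so
a negative-binomial count layer would add nothing the pipeline can detect.
The key structural knob is the per-copy upregulation factor `u`: autosomal
genes contribute two copies at the baseline rate, non-PAR X genes one
active copy at `u ×` the baseline rate, PAR genes two copies (both sex
chromosomes). This makes the mapping to the estimand analytic,

```
RXE_true = log2(u) − 1,
```

so `u = 2` means doubled transcription from the single X (RXE 0, ratio 1),
`u = 1` no compensation (RXE −1), and the default `u = 1.8` a partial
compensation of RXE ≈ −0.152, the regime reported for mammalian somatic
tissues. Because PAR genes carry two copies, removing them
(`XCI_SUBJECT`) shifts RXE slightly — upward whenever `u < 2` — which
reproduces the qualitative subgroup ordering seen in real tissues.

What the generator does *not* emulate: batch effects across sequencing
runs, gene–gene correlation, length-dependent quantification bias, isoform
structure, and tissue-specific expression programs. Passing recovery tests
therefore demonstrates that the estimators measure what they claim on data
satisfying their assumptions — not that any particular real tissue obeys
those assumptions.

```{r generator}
cfg <- synthetic_config(seed = 7)
ann <- generate_annotation(cfg)
expr <- generate_expression(ann, cfg)
samples <- generate_design(cfg)
compute_rxe(expr, ann, subgroup = c("ALL", "XCI_SUBJECT")) %>%
  group_by(subgroup) %>%
  summarise(mean_rxe = mean(rxe), .groups = "drop")
```

## Bootstrap differential expression

Diet-responsive genes are called by a stratified sample-level bootstrap,
suited to designs with few replicates and making no distributional
assumptions. For each of 200 replicates (configurable), sample columns are
resampled with replacement within each group, group means recomputed, and
the bootstrap fold change `FC_b = mean_alt / mean_ref` recorded with the
conventions `0/0 → 1`, `x/0 → +∞`, `0/x → 0`. The two-sided empirical
p-value is `2 × min(P(FC_b ≥ 1), P(FC_b ≤ 1))`, clipped to `[1/B, 1]` so
finite resampling never reports zero. The reported effect is the log2 ratio
of *observed* group means — ±∞ when one group's mean is exactly zero — and
a gene is significant when `|log2FC| > 1` and `p ≤ 0.05` (both
configurable; no multiple-testing correction by default, with a
Benjamini–Hochberg option). The resampling unit is the sample, not the
read: the package ingests gene-level TPM, and read-level resampling would
require alignments, which are out of scope. Published bootstrap DE tables
from read-level tools are consequently treated as format exemplars, not as
numeric oracles — their printed fold changes are not reproducible from
group means alone.

Two numerical properties are worth knowing:

* **Determinism and label symmetry.** Resampling indices are drawn per
  group in fixed alphabetical group order, so the same seed gives
  bit-identical results and swapping reference/alternative flips only the
  sign of `log2FC`, leaving p-values untouched.
* **Anti-conservativeness at small n.** The non-centered percentile
  bootstrap underestimates sampling variance by a factor of about
  `sqrt((n−1)/n)` per group; at n = 7 vs 4 the realized fraction of null
  genes with `p ≤ 0.05` is about 0.14, not 0.05 (the package's own null
  simulations and an independent single-gene oracle agree). The p-value
  alone should therefore not be used as a calibrated error rate at these
  group sizes; in practice the `|log2FC| > 1` gate does the heavy lifting,
  and with it the false-discovery proportion on planted-effect simulations
  is ~0 while sensitivity for |log2 effects| ≥ 3 is ~1.

## Group comparisons

Three conventional tests operate on derived statistics, each delegated to
the standard R implementations and checked against closed-form or
enumeration oracles in the test suite:

* `compare_rxe_by_sex()` — two-sample t-test on per-sample RXE, classic
  pooled-variance Student form by default (Welch optional), stratified by
  tissue by default (sexes are compared within the same somatic tissue;
  pooling is available via `by = NULL`).
* `compare_rxe_by_diet()` — two-sided Wilcoxon rank-sum. Exact enumeration
  when both groups have ≤ 8 untied values, otherwise the normal
  approximation with continuity and tie correction; fully tied data give
  p = 1 by convention.
* `anova_expressed_counts()` — one-way ANOVA on per-sample expressed
  X-linked gene counts across treatments, per tissue. Degenerate inputs
  are resolved by convention: zero between-group variation gives F = 0,
  p = 1; zero within-group variation with unequal means gives F = ∞, p = 0.

`activity_gene_count_correlation()` relates mean RGE to the number of
expressed genes per autosome (Pearson), flagging chromosomes whose
activity is driven by few highly expressed genes.

## Boxplot summaries

`summarize_group()` reproduces the Tukey construction used for
chromosome-level displays: hinges at the 25th/75th percentiles with linear
interpolation between order statistics (`quantile(type = 7)`, the plotting
default in R graphics systems), whiskers to the most extreme value within
1.5 × IQR of the hinges, and everything beyond returned individually with
its label. The alternative "95% confidence interval" whisker convention
sometimes quoted alongside 1.5 × IQR is deliberately not implemented — it is
ambiguous (CI of what?) and the IQR rule is the de facto standard.

## The pipeline and reproducibility

`run_pipeline()` chains the stages in fixed order — input (synthetic or
files), subgroup RXE + classification, RGE, boxplot summaries, bootstrap DE
with the X-linked subset, group tests — and writes a TSV/JSON bundle plus a
manifest with MD5 hashes, the seed and the package version. The master seed
drives the generator directly and the bootstrap via `seed + 1`; reruns with
the same configuration are byte-identical, which the test suite asserts on
the manifest hashes.

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config(
  synthetic = synthetic_config(),
  out_dir = "run1", seed = 1
))
glance(res)
```

## Problem sizes and numerical choices

The validation suite uses three scales, chosen as the smallest designs that
still pin down each property:

* analytic identities (RXE of −1/0, ratio 1) on constructed matrices of
  ~120–160 genes, where the expected values are exact;
* recovery of `RXE_true = log2(u) − 1` at the full default scale (20,519
  genes × 45 samples), averaged over 50 generator seeds: the X gene-set
  mean over 1,228 heavy-tailed genes has a per-dataset SD of ≈ 0.09 log2
  units, so individual datasets scatter but the 50-repeat mean is stable
  well within ±0.05;
* DE recovery and the null calibration on a reduced genome (3 autosomes ×
  ~1,050 genes + 150 X, 15 samples), where 200-replicate bootstraps over
  dozens of repeats remain fast while group sizes match the study design
  (7/4/4) that the small-n properties depend on.

Degenerate inputs are rejected loudly rather than patched: empty subgroup
gene sets, zero gene-set means, all-zero count columns and non-finite RXE
are errors that name the offending sample or set, because silently dropping
them would bias chromosome means.

## Known limitations

* RXE compares gene-set means; it does not model gene-length or GC bias
  within TPM, and inherits any quantifier's biases.
* The bootstrap p-value is anti-conservative at very small group sizes
  (see above); treat it as a ranking statistic there.
* PAR handling assumes the PAR catalogue is supplied; non-PAR escape genes
  remain in `XCI_SUBJECT`.
* The generator's noise magnitudes are chosen for test power, not fitted
  to tissues; absolute power estimates on real data require real
  dispersions.
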