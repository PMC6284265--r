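---
title: "Longitudinal gene-set reduction: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal gene-set reduction: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a longitudinal case/control expression experiment, every gene is measured
on every subject at several time points. The common practice of testing each
time point separately discards the dependence between a subject's repeated
measures and misses genes whose association with the phenotype is mild at any
single time point but accumulates across the trajectory. `longsamgsr` treats
each gene's trajectory as a *gene set* — its members are the gene's T
time-point measurements — and applies a gene-set screening plus set-reduction
strategy to select genes and then the specific time points that drive each
gene's association.

## The statistic

For gene g at time point t, the moderated two-sample statistic is

$$ d_t = \frac{\bar{x}_d(t) - \bar{x}_c(t)}{s(t) + s_{0t}}, $$

where $\bar{x}_d(t)$ and $\bar{x}_c(t)$ are the class means (diseased and
control), $s(t)$ is the pooled scatter
$s = \sqrt{\left(\tfrac{1}{n_d}+\tfrac{1}{n_c}\right)\tfrac{SS_d + SS_c}{n_d+n_c-2}}$
(the standard-error-scale pooled standard deviation familiar from the SAM
literature), and $s_{0t}$ is a small positive "fudge" constant that keeps
low-variance genes from dominating. Both $s(t)$ and $s_{0t}$ are estimated
per time point, since measurement variability can change over the course of
a study. The gene-level trajectory statistic is

$$ \mathrm{SAMGS}_g = \sum_{t=1}^{T} d_t^2 . $$

**Screening (step 1).** Significance of $\mathrm{SAMGS}_g$ is assessed by a
permutation test that relabels *subjects* — a subject's whole trajectory
moves between classes as a unit, so the within-subject correlation that
motivates the method is preserved under the null. Per-permutation fudge
constants are re-estimated (the literal application of the statistic to the
permuted labels). P-values use the add-one estimator
$p = (1 + \#\{b : \mathrm{null}_b \ge \mathrm{obs}\})/(B+1)$; when all
distinct relabelings can be enumerated the test switches to the exact
proportion. Genes are kept at FDR level `q_cutoff` (default 0.05) after
Benjamini–Hochberg adjustment.

**Reduction (step 2).** Within each selected gene, time points are ranked by
$|d_t|$ (ties broken toward the earlier time point; time points without
enough data are placed last and never enter the core). For
$k = 1, \dots, T'-1$, $c_k$ is the permutation p-value of the *residual*
subset — the sum of $d_t^2$ over the time points not among the top k —
against the same stored permutations used in step 1. The core size is the
smallest k with $c_k > c_{\mathrm{cutoff}}$; if none exists the whole
available trajectory is kept. This enforces a monotone-entry rule: a time
point can only enter the core if every time point with a larger $|d|$ is
already inside.

**Tuning.** $c_{\mathrm{cutoff}}$ is treated as a tuning parameter on the
grid 0.05, 0.10, ..., 0.50 and chosen by 5-fold cross-validation, stratified
by phenotype at the subject level. Screening is re-run inside every training
fold, so selection bias cannot leak into the CV error; the fold error is the
misclassification rate of averaged per-time-point SVM posteriors on the
held-out subjects (a fold with an empty feature table contributes the
uninformative error 0.5). Ties in CV error break toward the smallest
cutoff, which yields the smaller feature set. After tuning, the final model
is one full-data run at the chosen cutoff.

## Evaluation

A selected feature table is turned into per-time-point classifiers: at each
time point with at least one selected gene, a linear support vector machine
(cost 1 by default) is fit on that time point's expression restricted to its
genes, and posterior probabilities are calibrated by a sigmoid fit — a
logistic regression of the training labels on the SVM decision values. We fit
the sigmoid ourselves rather than using the SVM library's built-in
calibration because the latter's internal cross-validation is not
seed-controllable, and bit-for-bit reproducibility is a design requirement.
Time points with no selected genes contribute a flat posterior of 0.5. Each
subject's per-time posteriors are averaged (available-case) and the averaged
posterior feeds four metrics:

* **misclassification error** at threshold 0.5 (0 optimal),
* **GBS** (generalized Brier score): mean squared difference between the
  posterior and the 0/1 label (0 optimal),
* **BCM** (belief confusion metric): mean posterior probability assigned to
  the true class (1 optimal),
* **AUPR**: area under the precision–recall curve by the step-wise,
  non-interpolated sum, diseased class positive (1 optimal).

GBS and BCM are reconstructions: the upstream literature names the metrics
and states their ranges and optimum directions without printing formulas.
The definitions used here are the unique natural choices matching every
stated property, but other definitions with the same range and direction are
conceivable; comparisons across implementations should check this.

## Key numerical fact: permutation granularity vs. FDR control

The smallest attainable add-one p-value is $1/(B+1)$, so the smallest
attainable BH-adjusted q-value on a panel of G genes is about $G/(B+1)$ at
rank 1. **Selection at `q_cutoff` is therefore only possible when
$B \gtrsim G/q_{\mathrm{cutoff}}$**, and a comfortable margin (several times
that) is needed before the q-value reflects the true tail probability rather
than the estimator floor. With the default `q_cutoff = 0.05`, a
1,000-gene panel needs tens of thousands of permutations before a lone
causal gene can pass screening. This is an intrinsic property of
permutation-based FDR screening with sparse signals, not an implementation
artifact; real panels with correlated genes are more forgiving because
co-selected genes raise the BH rank. The engine computes all permutations of
a time point in a single matrix product, so large B is affordable
(G = 500, B = 20,000, T = 5 runs in seconds).

## The fudge constant

The upstream description calls $s_{0t}$ only "a small positive constant".
Two policies are provided:

* `median` (default): the median of the per-gene pooled scatters at that
  time point. Parameter-free, scale-equivariant (so $d$ is invariant to
  rescaling the expression matrix), and standard across SAM-family software.
* `percentile`: the classical percentile search — candidate quantiles of the
  scatter distribution are scored by the coefficient of variation of the
  spread of $d$ across scatter deciles, and the minimizer is used.

The choice of $s_0$ estimator is the largest numeric-reproducibility unknown
when comparing against other implementations of SAM-type statistics; results
in this package default to the median policy and state so.

## Missing data

Missingness is carried as an explicit mask, never as sentinel values. Every
(gene, time) cell is computed available-case; a cell with fewer than two
measured subjects in either class is flagged unavailable, contributes zero
to trajectory sums, is excluded from the reduction ordering, and is counted
in a warning. Subjects missing a time point are skipped by that time point's
classifier and their posterior average runs over the time points they do
have.

## The synthetic-data generator

`generate_base_expression()` emulates summary microarray intensities: gene
means are drawn log-normal around 7 (log-scale units, `sdlog` 0.15), gene
SDs log-normal around 0.5 (`sdlog` 0.4), and each subject's trajectory
follows a stationary AR(1) with lag-1 correlation `rho = 0.6` by default —
trajectories are substantially autocorrelated, which is the premise of
treating them as sets. An optional block structure gives groups of genes a
shared latent trajectory, emulating the co-expressed redundant features that
inflate selection in real panels. Outcomes are generated by a logistic model
on chosen (gene, time) covariates: scenario 1 places coefficients 0.18,
0.57, 0.29, 0.41 on one gene at times 1–4 (a joint, accumulated-over-time
effect) plus 1.02 on a second gene at time 3 alone; scenario 2 places 0.56
and −0.91 on two genes at times 1 and 5. With synthetic bases the covariates
are standardized before the coefficients apply, so the printed values are
per-SD log-odds; with a user-supplied real expression pool the covariates
are centered but kept in raw units (an uncentered no-intercept logit on
intensities near 7 would saturate at p = 1). Noise genes are redrawn
per replicate.

What the generator does *not* emulate: heavy-tailed intensity distributions,
array batch effects, probe-level artifacts, and — unless block correlation
is switched on — the pervasive inter-gene correlation of real transcriptomes.
Passing tests on these synthetics therefore demonstrates correctness of the
machinery and calibration under idealized sampling, not field performance on
a specific platform.

## Problem sizes used by the test-suite and acceptance studies

The packaged studies are sized for a desk-scale single-CPU run: null
calibration uses G = 500 genes, 20 + 20 subjects, T = 3, B = 500; recovery
studies use G = 200 panels with 18 + 25 subjects, T = 5 and B = 20,000
permutations (comfortably past the granularity bound above); replicate
studies run 10 replicates of 300-gene scenarios. These are the package's
chosen study conditions; scaling any of them up is a matter of the same
calls with larger arguments.

## Design choices on points the method statement leaves open

* **Permutation unit**: subject-level relabeling (trajectories move whole).
  Per-sample relabeling would destroy the within-subject dependence the
  method exists to exploit.
* **Step-2 null**: the reduction step reuses the step-1 permutations and
  their per-permutation fudge constants, making the two steps mutually
  consistent and the whole pipeline deterministic given one seed.
* **q-values**: Benjamini–Hochberg by default (monotone, parameter-free);
  Storey's $\pi_0$ correction at $\lambda = 0.5$ available as a policy
  switch.
* **Tie-breaks**: equal $|d_t|$ ranks resolve toward the earlier time point;
  equal CV errors resolve toward the smaller cutoff.
* **Truncation of longer follow-up** (e.g. aligning cases and controls to a
  common last time point) is treated as caller-side data preparation, not
  part of the method.
* **Final-model convention**: tune by CV, then fit once on the full training
  data at the tuned cutoff.

## Known limitations

* Single-causal-gene power at FDR 0.05 is limited on large independent
  panels (see the granularity section); the method is at its best when
  several genes carry signal or genes are correlated.
* A gene selected for a joint-over-time effect can still be significant at
  its strongest single time point; the regime where the trajectory test
  detects what per-time tests cannot is a window of moderate per-time
  effects, and outside that window the two analyses agree.
* The reduction's residual p-values inherit the granularity of B; with few
  permutations, $c_k$ moves in steps of $1/(B+1)$ and cutoffs inside one
  step are indistinguishable.
* Binary phenotypes only; no paired designs, no multi-class extension, no
  survival outcomes.
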