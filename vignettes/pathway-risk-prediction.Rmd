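---
title: "Hybrid gene-set and single-gene survival risk prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid gene-set and single-gene survival risk prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Expression-based survival predictors built from individual genes are fragile:
with tens of thousands of candidate genes, a hundred-odd patients and heavy
censoring, the genes that screen as prognostic in one cohort often fail to
screen in the next. Gene sets — pathways, regulons, cytogenetic bands —
average measurement noise over their members, so a set-level expression index
is a more reproducible feature than any one member gene. But curated
collections are incomplete: genuinely prognostic genes can belong to no
annotated set, and a predictor restricted to sets never sees them.

`pathrisk` implements the hybrid strategy: summarize every gene set into a
per-sample expression index, treat every single gene as a pseudo gene set
with one member, and let set-level and gene-level features compete in one
supervised-principal-components pipeline for censored survival.

# The model

## Gene-set expression indices

Let $e_{ij}$ be the expression of gene $i$ in sample $j$, with training mean
$\mu_i$ and standard deviation $\sigma_i$ (sample SD, $n-1$ denominator;
constant genes are removed). Standardized values are
$e'_{ij} = (e_{ij} - \mu_i)/\sigma_i$.

**Step 1 (maxmean).** For gene set $g$ with $N_g$ member genes present in
the matrix,
$$u_{gj} = \mathrm{absmax}\!\left[\tfrac{1}{N_g}\sum_{i \in GS_g}(e'_{ij})_+,\;
\tfrac{1}{N_g}\sum_{i \in GS_g}(e'_{ij})_-\right],$$
where $(x)_+ = \max(x, 0)$, $(x)_- = \min(x, 0)$ and absmax returns the
argument of larger magnitude. The maxmean summary responds to coherent
up-shifts, coherent down-shifts, and split up/down behaviour of a set's
members, unlike a plain mean. When the positive and negative parts tie in
magnitude absmax returns its first argument, the positive part; a tie with
both parts nonzero is possible (members $(1, -1)$ give parts $\pm 0.5$), and
this convention resolves it deterministically.

**Step 2 (rescaling).** $u_{gj}$ is standardized across training samples to
$u'_{gj}$ and rescaled to
$$x_{gj} = u'_{gj}\sqrt{\tfrac{1}{N_g}\textstyle\sum_i \sigma_i^2}
 + \tfrac{1}{N_g}\textstyle\sum_i \mu_i ,$$
so that across training samples each set feature has exactly the average
mean and the average variance of its member genes. This puts set features
and raw single-gene features on one scale, which is what makes the hybrid
pool coherent. Two consequences are worth noting and are enforced by tests:
a one-member set reproduces its gene's raw expression exactly, and the
mean/variance contract holds to numerical precision under the $n-1$ SD
convention used throughout.

All Step 1/Step 2 parameters — $\mu_i$, $\sigma_i$, the mean and SD of
$u_g$, and the rescaling targets — are estimated on training samples only
and replayed verbatim on test samples. The method never re-estimates
anything from test data.

## Feature screening: the Cox score

Every feature (set index or raw gene) is scored by the standardized score
statistic of the Cox partial likelihood at $\beta = 0$:
$$s = \frac{U(0)}{\sqrt{I(0)}}, \qquad
U(0) = \sum_{k}\Big(\sum_{\text{events at }t_k} x_j - d_k\,\bar{x}_{R_k}\Big),\qquad
I(0) = \sum_{k} d_k\,\mathrm{Var}_{R_k}(x),$$
summing over distinct event times $t_k$ with $d_k$ tied events and risk set
$R_k$ (Breslow convention; censored samples remain at risk through their own
time). Under the null the statistic is asymptotically standard normal, so
magnitudes are comparable across features; screening thresholds $|s|$.

## Threshold selection by repeated cross-validation

Candidate thresholds are 20 evenly spaced quantiles (50th–99th percentile)
of the full-training $|s|$ distribution — scale-free and bounded in cost.
The training set is split into 3 event-stratified folds; for each fold and
threshold the *entire* pipeline (standardization, summarization, scoring,
selection, predictor fit) is re-estimated on the in-fold two-thirds and the
held-out third is scored by the Cox likelihood-ratio statistic of its
predicted risk — the quantity supervised principal components optimizes.
The partition is redrawn 100 times (default) and performance averaged;
ties between thresholds go to the larger (more parsimonious) one. The final
feature list applies the chosen threshold to scores recomputed on the full
training set. Averaging across repeats, rather than voting on per-repeat
winners, is used because the per-repeat surface is noisy and averaging uses
all of it.

## The membership-weighted principal component

Selected features $x_1,\dots,x_n$ with member counts $N_1,\dots,N_n$
(single genes: $N_i = 1$) are centered at their training means and stacked
into the weighted matrix
$$\mathrm{diag}(N_1,\dots,N_n)\,[x_1^\top; \dots; x_n^\top].$$
The first right-singular direction of this matrix gives per-sample predictor
scores; the unit left-singular vector is the stored loading. With all
$N_i = 1$ this is conventional PCA (a tested identity). The weights
deliberately emphasize set features summarized from many members; the
variance inflation that $N_i$ (rather than $\sqrt{N_i}$) implies is part of
the method, and a clearly marked non-default `weight = "sqrt_n_members"`
variant exists for comparison only.

Centering before the SVD is a design choice the method description leaves
open; uncentered "PCA" is not principal component analysis, so centering at
training means (replayed at test time) is used. The SVD sign is arbitrary,
so the orientation is fixed by the training data: the sign is chosen so the
Cox coefficient of the training risk score is non-negative — higher risk
always predicts shorter survival. Test-sample risks are the projections of
the rebuilt, centered, weighted test features onto the stored loading.

## Evaluation

Four statistics are computed on (risk, survival) pairs: the Cox
likelihood-ratio statistic (Breslow ties), Harrell's C (a pair is usable
when the sample with the strictly shorter time has an observed event; risk
ties count 1/2), the median-split two-sample log-rank p-value (ties at the
median go to the low-risk group), and $R^2$. The method description reports
an $R^2$ without defining it; the Cox–Snell form $1 - \exp(-\mathrm{LR}/n)$
is used here because it is computable from the already-reported likelihood
ratio and matches the magnitude scale of the reported values. All Cox fits
use Breslow ties for internal consistency with the score statistic.

# The synthetic cohort generator

Real benchmark cohorts are external data; the generator provides cohorts
whose *structure* matches what the method assumes, so every claim the
package makes is testable offline.

Expression follows a sparse latent-factor model. Every annotated gene set is
a co-expressed block: its member genes load (loading $\ell$) on a set-specific
latent factor, plus i.i.d. noise (SD $\nu$) and a per-gene baseline mean and
scale. Only `n_informative` sets have hazard-linked factors; the remaining
sets are real but non-prognostic co-expression modules — a deliberate
feature, because the hardest part of single-gene screening in real data is
that high-variance correlated modules exist everywhere, not just where the
outcome signal is. Hazard factors are mutually correlated through a shared
per-sample severity axis (`factor_cor`), reflecting co-activated pathways in
one disease process; with fully independent pathway factors a one-component
predictor could only ever represent a single pathway and comparisons between
feature pools would collapse to noise. Within-set member correlation has the
closed form $\ell^2/(\ell^2+\nu^2)$, which the test suite checks against the
realized value.

Incomplete annotation (`orphan_fraction` $q$) is modeled as *hidden* blocks:
$\mathrm{round}\big(\tfrac{q}{1-q}\,\texttt{n\_informative}\big)$ additional
hazard-linked co-expression blocks whose genes appear in the matrix but in
no annotated set, so the requested fraction of signal genes is invisible to
set-level features. Hidden signal must be non-redundant with annotated
signal — orphan genes that merely echo an annotated factor would make the
hybrid-versus-geneset comparison vacuous. `n_orphan_genes` additionally
plants standalone single signal genes (a hidden block of size one).

Survival times are exponential with rate
$\lambda_0 \exp(\eta)$, $\eta = \beta \sum_s f_s$ over hazard factors;
independent exponential censoring has its rate solved numerically
(`uniroot`) so the expected censoring fraction hits the target. One seed
drives the entire draw.

**Default conditions.** `n_genes = 3000`, `n_train = n_test = 150`,
`n_sets = 200` with 10–50 members, `n_informative = 5`, $\ell = 0.3$,
$\nu = 1$, `factor_cor = 0.3`, $\beta = 0.6$, censoring 30%. These emulate a
filtered microarray cohort at the scale of the smallest benchmark the method
targets (about 150 patients): each signal gene correlates with its pathway
factor at about $0.29$ — individually weak, the regime the method was
designed for — while a 30-member set index correlates at about $0.9$; the
resulting test-set C indices mostly land between $0.6$ and $0.78$
(occasional seeds fall lower when a lucky decoy set passes the threshold
and dominates the weighted component), bracketing the range reported for
real cohorts of this size. The generator does *not* emulate
platform-specific noise, probe-level effects, batch structure, non-normal
margins, or non-proportional hazards; passing tests demonstrate correct and
robust behaviour under the factor-model idealization, not performance on any
particular real data set.

# Numerical choices and degenerate inputs

* Sample SD ($n-1$) everywhere; the mean/variance conservation contract
  holds exactly under this one convention.
* Genes with zero variance are removed before any summarization and cannot
  become features; sets whose members are all absent, or whose maxmean
  summary is constant across training samples, are dropped with a log record.
* Set members absent from the expression matrix are intersected out at
  feature-building time and $N_g$ counts only present members — absent genes
  contribute no measurement. Sample-ID mismatches between expression and
  survival are an error, never a silent join.
* Features whose Cox score has numerically zero information are skipped with
  a record; a score threshold that selects nothing is an error surfaced to
  the caller.
* Cross-validation folds are event-stratified so every fold carries at least
  two events; a repeat that cannot satisfy this is redrawn up to a cap.
  Held-out performance of an empty selection, or of a degenerate held-out
  risk, scores 0.
* Threshold ties resolve to the larger threshold; absmax ties resolve to the
  positive part; median-split risk ties go to the low-risk group. All three
  rules are arbitrary but fixed and tested.

# Problem sizes used by the test suite

The repeated-CV defaults (3 folds × 100 repeats × 20 thresholds) are what
the exported functions use. The package's own simulation studies scale the
CV down — 3–10 repeats and 6–8 thresholds — because their conclusions
(type-I calibration of the end-to-end pipeline, recovery of planted sets,
ordering of the three feature pools, split-stability of scores) are
properties of the procedure, not of the repeat count, and the reduced
settings keep each study to a few minutes: 200 end-to-end null replicates at
$n = 100$; 20 seeds at the default benchmark scale for recovery, for the
orphan-fraction comparison of the three modes, and for split robustness.

# Known limitations

* Only the first principal component is used, as the method prescribes;
  multi-component variants are out of scope.
* The $N_i$ weighting is implemented verbatim; it can let one very large
  selected set dominate the component.
* The generator's factor model is linear-Gaussian with exponential survival;
  conclusions about robustness to model misspecification cannot be drawn
  from it.
* Probe-to-gene mapping, cross-platform batch correction and the curation of
  gene-set collections are upstream concerns the package does not address.
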