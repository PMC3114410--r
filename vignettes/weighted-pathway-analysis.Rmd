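---
title: "Weighted pathway analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted pathway analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathweight)
```

## The model

`pathweight` tests whether a gene set (pathway) is associated with a binary
phenotype in an n-sample, p-gene expression study.  For one pathway of m
genes with expression matrix $X$ (n × m) and labels $Y \in \{0,1\}^n$
(1 = disease), the global test views $Y$ through a logistic regression on
the pathway's linear predictor with random coefficients of common variance
$\tau^2$; testing no association ($\tau^2 = 0$) leads to the score-type
statistic

$$Q = \frac{(Y-\mu)' R\, (Y-\mu)}{\mu_2}, \qquad R = \tfrac{1}{m} X X',$$

with $\mu = \bar Y$ and $\mu_2 = \mu(1-\mu)$.  $R$ is proportional to the
covariance of the random effects, so $Q$ is large exactly when the
between-sample similarity of expression aligns with the similarity of
outcomes.  We use $\mu_2 = \mu(1-\mu)$, the null variance of a binary $Y$,
as in the original global-test formulation; the notation $1/\mu 2$ in some
presentations is ambiguous between this and $1/\mu^2$, but since either is
constant for fixed $Y$, permutation p-values are identical under both
readings and only Q's absolute scale differs.

Significance is assessed by permuting $Y$: $p = \#\{b: Q_b \ge Q_{obs}\}/B$.
This is the plain frequency estimator — $p = 0$ is attainable and should be
read as $p < 1/B$.  No "+1" correction is applied, because the screening
procedures built on these p-values (ranking, top-k selection, counting
$p < .05$) compare pathways to each other on a common grid rather than
controlling a single test's size.  For $n \le 10$,
`exact_permutation_p_value()` enumerates all $\binom{n}{n_1}$ label
arrangements and serves as the exact reference.

A subtlety worth recording: with balanced classes the complementary
labeling ($0 \leftrightarrow 1$) always has exactly the same $Q$, so the
smallest attainable exact p-value is $2/\binom{n}{n/2}$, not
$1/\binom{n}{n/2}$.  For the $\ge$ comparison to count such exact ties
correctly in floating point, the observed labels are evaluated through the
same matrix multiplication as the permuted ones.

## Weighting schemes

All four schemes replace $X$ by a weighted $wX$ before computing $Q$:

* **absT** — $w_j = |T_j| / \sum_k |T_k|$ with $T_j$ the two-sample
  t statistic of gene $j$.  We use the pooled-variance (classical
  equal-variance) form as the textbook default; Welch is available via
  `flavor = "welch"`.  A gene with zero within-class variance but a real
  mean difference has infinite $|T|$; we cap it at the largest finite
  $|T|$ in the pathway so the normalization stays defined, and warn.
* **Qdiff** — $w_j \propto |Q - Q_{(-j)}|$, the change in $Q$ when gene $j$
  is dropped.  For $m = 1$ the leave-one-out is undefined and the gene
  receives weight 1.  Both closed-form schemes return weights that are
  nonnegative and sum to one.
* **RWV** — random search over per-gene weight vectors: each candidate
  draws $m$ values uniformly in a range (default $[0.1, 1]$), then
  resamples $m$ of them with replacement, and the candidate minimizing the
  pathway's permutation p-value is kept.  The two-step draw is implemented
  literally as specified (the resampling step allows repeated values in a
  candidate); `simple_draw = TRUE` collapses it to a single draw.
* **RWM** — the same search over $n \times m$ weight matrices applied
  elementwise.  The larger space lets RWM match or beat RWV at equal
  iteration counts, which our paired-seed tests confirm.

Search mechanics that matter for correctness:

* The **uniform candidate is evaluated first**, so the reported best
  objective never exceeds the uniform objective — improvement is
  guaranteed by construction, and what is empirical is only its size.
* All candidates within one search share **one fixed permutation stream**;
  otherwise Monte-Carlo noise between candidates would corrupt the argmin
  (a candidate could "win" by drawing a lucky stream).  A consequence worth
  noting: because the p-value is invariant to uniform rescaling of $X$, a
  candidate proportional to all-ones scores exactly the uniform objective.
* Ties on the objective (common at small $B$, where p-values live on a
  grid of width $1/B$) keep the first-found candidate unless the
  challenger has strictly larger observed $Q$.
* The default iteration count is 25,000, past the point where convergence
  curves flatten on the data sizes this package targets; tests and the
  convergence sweep use far smaller counts.  `iteration_sweep()` evaluates
  prefixes of one growing candidate stream per pathway, so the curve is
  non-increasing by construction, cheap, and deterministic per seed; it
  averages over all screened pathways.

## The forest score

The alternative pathway score is the out-of-bag error of a bagged
classification forest grown on the pathway matrix (via `randomForest`,
with the conventional defaults mtry = ⌊√m⌋, unlimited depth, bootstrap
size n; these are conventions of that lineage, not estimates from data).
Samples never out of bag — possible at very small tree counts — are
excluded from the denominator and counted in the result.  Errors are
reported as proportions in [0, 1].

A per-gene weight multiplies a column by a positive constant, a strictly
monotone transformation that preserves every attainable split threshold,
so vector-weight schemes (absT, Qdiff, RWV) cannot change OOB error; the
package rejects those combinations rather than silently reporting
uniform-equal scores, and a test verifies the invariance empirically at a
fixed forest seed.  Under RWM, every candidate forest reuses the same tree
seed so that candidate comparisons isolate the weights from forest
randomness.

## The simulator

`simulate_pathway()` draws multivariate-normal expression from a
`pathway_model` (mean vector, covariance matrix, optional disease-group
mean shift), so a simulated pathway retains the mean and full covariance —
hence correlation — structure of whatever data the model was estimated
from with `estimate_moments()` (sample moments, denominator n − 1, tiny
negative eigenvalues clipped to zero).  Labels split samples into a normal
first half and disease second half; even sizes are exactly balanced, odd
sizes differ by one with a warning.  The default shift is zero: both
groups are identically distributed, and the exact permutation p-values are
verifiably super-uniform over regenerated datasets.  A nonzero shift is
the explicit mechanism for planting differential expression.

`make_synthetic_study()` builds a whole screening study: i.i.d. standard
normal background over a gene universe, random gene sets (sampled without
replacement within a pathway, overlapping freely across pathways, as real
collections do), and a mean shift of `shift_size` on half of each
informative pathway's genes in the disease group, with the ground truth
returned.  The defaults — 500 genes, 20 pathways of 10–26 genes, 50
samples balanced, 3 informative pathways, shift 2 — are the study
conditions used by the package's own end-to-end checks: pathway sizes
bracket the 21- and 26-gene pathways typical of curated collections,
n = 50 is the middle of the 30/50/100 ladder the simulator is meant to
cover, and a shift of 2 background standard deviations on half the member
genes makes planted pathways unambiguously detectable at that n.

What the simulator does **not** emulate: heavy-tailed or count-valued
expression, gene-gene correlation in the background (only within-pathway
structure via `pathway_model`), batch effects, and label noise.  Passing
tests on this generator demonstrate the statistical machinery, not
robustness to those real-data features.

Two consequences of the design are visible in results and deliberate.
First, because gene sets overlap, planted genes leak signal into
nominally null pathways — as in real collections, where "null" is a
property of genes, not of sets.  Second, at the default shift the
informative pathways' p-values saturate at 0 for every scheme, so
scheme comparisons on the top of the ranking are often ties; comparisons
are therefore stated as ≤ (with ties allowed), and the significant-count
metric, which integrates over the whole collection, is the more
discriminating summary at these conditions.

## Ranking and reports

Pathways are ranked by score ascending with **competition ranking**
("1224": tied scores share the smallest applicable rank, the next rank
skips the block), and listed in collection file order within ties.
`select_top_k(include_ties = TRUE)` extends the selection through the tie
block containing the k-th row — never splitting a block — which is how a
nominal top-20 can legitimately return 33 rows when ranks 20+ are tied.
Significance counts use strict `p < alpha` with no multiplicity
correction; this mirrors the screening practice the package implements
and is a caveat, not a recommendation — the counts compare schemes, they
do not control FDR.

`rank_changes()` reports pathways whose rank improves by at least a
threshold between two screens over the same universe; `find_overlaps()`
lists pathways recurring in the top-k of at least `min_schemes` schemes.

## Prediction evaluation

`loocv_rate()` computes leave-one-out cross-validated accuracy for LDA,
linear-kernel SVM, polynomial-kernel SVM, and KNN on a pathway's matrix.
Hyperparameters are conventional defaults, configurable and not tuned:
KNN k = 3, polynomial degree 3, SVM cost 1, LDA with pooled covariance.
Features are not standardized unless `standardize = TRUE` — standardizing
inside each training fold is exposed but off by default since the input
is assumed normalized.  Degenerate folds (single-class training data,
classifier failure on constant features) fall back to the training-fold
majority class with a warning, ties toward class 0.

One caveat surfaced rather than hidden: a per-gene weight vector leaves
scale-invariant classifiers (LDA) exactly unchanged but can change
scale-sensitive ones (KNN, SVM), so the often-stated claim that vector
weights cannot affect single-gene classification holds only for the
former.  We compute rates faithfully on the weighted data either way;
only matrix (RWM) weights are applied by default in top-k evaluation,
as the only scheme whose weights vary within a gene.

## Numerical choices and degenerate inputs

* Q is computed as $\|X'(Y-\mu)\|^2/(m\,\mu_2)$ — one BLAS call per batch
  of label vectors; permutation batches are evaluated jointly with the
  observed labels so exact ties are counted exactly.
* Single-class labels, zero-gene matrices, and invalid weight ranges are
  rejected with informative errors; empty pathway/dataset intersections
  signal a classed condition that screens catch, log, and report as
  skipped rather than ranked.
* Seeds: every random operation takes an explicit seed and restores the
  caller's RNG state; screens derive one sub-seed per pathway from the
  base seed so pathway scores are independent of collection order and of
  each other's computations, and all derived seeds stay within 32-bit
  integer range.
* Problem sizes in the shipped tests are deliberately small (hundreds of
  permutations, tens of search iterations, ≤1000 trees); they exercise
  the same code paths as production-scale settings, whose defaults
  (10,000 permutations, 25,000 iterations) remain the documented
  recommendation for real screens.

## Known limitations

* Binary outcomes only; no continuous or survival phenotypes, and no
  asymptotic null for Q — permutation only.
* Raw p-values throughout; multiple-testing control is out of scope.
* Gene matching is exact string equality: no probe collapsing, aliasing,
  or ortholog mapping.
* Weight searches are plain random search by design — no gradient or
  annealing refinement — so reported "optimal" weights are best-found,
  not global optima, and at small permutation counts the minimized
  p-value is an optimistically biased estimate of the weighted pathway's
  significance (weights chosen to minimize p on the same data that
  evaluates p).  Rankings across pathways under a common scheme remain
  comparable; the absolute minimized p-values should not be read as
  calibrated significance levels.
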