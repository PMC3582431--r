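---
title: "Methods: multiclass relevance units classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiclass relevance units classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrum)
```

This vignette is the package's account of its statistical machinery: the
binary classifier, how complexity and kernel width are chosen, how the
multiclass decomposition and its decoders work, the numerical choices made
where the design was genuinely open, and what the synthetic fixtures do and
do not establish.

## The binary relevance units classifier

The binary unit of the package models the positive-class posterior as a
sigmoid over a sparse kernel expansion,

$$P(C_+ \mid x) = \sigma\!\Big(\sum_{i=1}^{M} w_i\, k(x, u_i) + b\Big),
\qquad k(x,u) = e^{-\gamma\|x-u\|^2},$$

where the $u_i$ are *relevance units*: cluster centers found by unsupervised
K-means on the training features, not selected training points. This is the
key structural difference from support-vector machines — model size $M$ is
fixed before supervised training, is typically far smaller than the number
of support vectors a comparable SVM would keep, and makes prediction cost
$O(M)$ per instance per binary problem.

With the units and $\gamma$ frozen, the design matrix
$\Phi_{nm} = k(x_n, u_m)$ (plus an unpenalized bias column) is fixed, and
fitting $(w, b)$ is penalized logistic regression: we minimize the log loss
plus $\tfrac{\alpha}{2}\|w\|^2$. Two standard devices complete the fit:

* **Damped Newton / IRLS** for the weight solve: tolerance $10^{-8}$ on the
  gradient max-norm, at most 100 iterations, step halving whenever a full
  Newton step would increase the objective. The IRLS weights
  $p_n(1-p_n)$ are floored at $10^{-12}$; a singular inner solve is
  reported as an error rather than silently regularized.
* **Evidence (empirical Bayes) update for $\alpha$**: between weight
  solves, $\alpha \leftarrow \gamma_{\mathrm{eff}} / \|w\|^2$ with
  $\gamma_{\mathrm{eff}} = \sum_j \lambda_j/(\lambda_j+\alpha)$, the
  $\lambda_j$ being eigenvalues of the unpenalized-loss Hessian restricted
  to the weight block. $\alpha$ starts at 1, is clamped to
  $[10^{-10}, 10^{10}]$, and the alternation stops when its relative change
  drops below $10^{-3}$ or after 100 cycles, after which the weights are
  re-solved once at the final $\alpha$ so the returned solution is
  stationary for the objective it reports. The error/complexity trade-off
  therefore needs no cross-validation.

This training procedure is this package's own reconstruction of the
relevance-units approach from its published sketch ("structural risk under
log loss" with an empirical-Bayes trade-off parameter); the exact historical
solver is not reproducible from public sources, so the standard, fully
reproducible machinery above is used and documented as such. On data with
no class signal the evidence alternation can oscillate without meeting the
$10^{-3}$ tolerance; the fit then returns the last iterate with a warning,
which is expected behavior, not failure.

Predictions are clamped to $(10^{-12}, 1-10^{-12})$ so that log-space
decoding downstream never sees an exact 0 or 1.

Feature standardization (per-column z-score, parameters stored in the
model) is on by default for generic tabular data because the Gaussian
kernel is scale-sensitive; it should be turned off for k-mer frequency
features, which are already normalized onto simplices.

## Choosing M and gamma

For each candidate $M$ in a doubling grid $\{2, 4, 8, \dots\}$ capped at
$\min(512, N/2)$, K-means (Lloyd's algorithm, 5 seeded restarts, initial
centers drawn uniformly from the distinct data rows) clusters the pooled
unlabeled features. The clustering is scored by an AIC under a
hard-assignment isotropic Gaussian mixture reading: shared variance
$\sigma^2 = \mathrm{SSE}/(Nd)$, mixing proportions $n_m/N$, giving

$$\log L = \sum_m n_m \log(n_m/N) - \frac{Nd}{2}\big(\log(2\pi\sigma^2)+1\big),
\qquad \mathrm{AIC} = 2\big(Md + (M-1) + 1\big) - 2\log L.$$

The probabilistic reading of the clustering was an open design point; the
hard-assignment shared-variance mixture is the simplest standard choice,
and only the *selection behavior* (which $M$ wins), not the absolute AIC
value, matters downstream. Ties go to the smaller $M$. The kernel width is
then $\gamma = 1/(2 d_{\max}^2)$ with $d_{\max}$ the maximum pairwise
distance among the selected centers — an intentionally cheap heuristic
whose value is that it requires no supervised tuning. One $(M, \gamma,
\text{units})$ triple is selected once per dataset and shared by **all**
binary classifiers of the multiclass model.

## Coding matrices

A $K$-class problem becomes $L$ binary problems through a coding matrix
over $\{1, 0, \Delta\}$; $\Delta$ marks classes omitted from a problem's
training. Validity requires unique rows and columns, no all-$\Delta$ row,
and both symbols present in every column. One-versus-rest is the $K \times
K$ identity pattern; all-pairs has one column per unordered class pair
(positive the smaller index, negative the larger, rest omitted).

Random matrices are generated column-wise (dense: 0/1 uniform; sparse:
$\Delta$ with probability 1/2, 0 and 1 each 1/4 — the established
random-sparse convention), invalid columns being redrawn and row-level
violations triggering a candidate restart, within a bounded retry budget.
From a pool of candidates (default 100) the one **maximizing** the minimum
pairwise row distance is kept, under the modified Hamming distance in which
a position costs 0 on agreement, 1 on disagreement, and $\tfrac12$ whenever
either symbol is $\Delta$ (including $\Delta$ vs $\Delta$ — the literal
reading of the cost table; this affects only candidate ranking, never
prediction-time decoding, since binarized predictions contain no
$\Delta$). Maximizing the minimum row distance is the classical
error-correcting design criterion. A column and its bit-complement are
*not* treated as duplicates; only literal uniqueness is enforced. Note that
column uniqueness caps dense codes at $L \le 2^K - 2$ usable columns.

## Decoding

**Hard decoding** binarizes the $L$ outputs at 0.5 and returns the class
whose code row is nearest in modified Hamming distance; ties go to the
smallest class index.

**Naive decoding** assumes the $L$ binary classifiers err independently,
giving
$$P(C_k \mid x) \propto \prod_{i:\,M_{ki}\neq\Delta}
g_i(x)^{M_{ki}}\big(1-g_i(x)\big)^{1-M_{ki}},$$
accumulated in log space with outputs clipped to $[10^{-12}, 1-10^{-12}]$
and normalized by a max-subtracted softmax (mathematically identical to
normalizing the raw products, numerically safe). The work is linear in
$L$, which is what makes this decoder suitable for millions of reads. The
independence assumption is the decoder's crux: it is plausible under
all-pairs and one-versus-rest decompositions but fails badly under random
codes, where the Bradley-Terry decoder should be preferred — the package's
own cross-decoder tests mirror exactly this pattern.

**Generalized Bradley-Terry decoding** estimates $p$ by minimizing
$$-\sum_{i=1}^L N_i\Big(\hat r_i \log\frac{q_i^+}{q_i} +
(1-\hat r_i)\log\frac{q_i^-}{q_i}\Big),$$
with $q_i^+, q_i^-, q_i$ the summed posteriors of each problem's positive,
negative and involved classes and $N_i$ the number of training instances
the problem saw. Starting from uniform $p$, a multiplicative update sweeps
all classes simultaneously, renormalizes, and repeats until the largest
per-class change falls below $10^{-8}$ or 1000 sweeps elapse; the $q$ sums
are floored at $10^{-12}$. The update is the canonical minimizer for this
objective and is stated fully in `?decode_gbt`, so no external source is
needed. Non-convergence is reported alongside the result rather than
raised: under general decompositions the iteration is not guaranteed to
converge. The convergence tolerance was an open choice; $10^{-8}$ makes the
consistency-recovery tests sharp without measurable cost at these problem
sizes.

Prediction attaches a rejection rule: the argmax class is assigned only if
its posterior reaches the threshold, otherwise the instance is
`UNCLASSIFIED`. Hard decoding produces no posterior, so requesting a
positive threshold with it is an error by design.

## Evaluation protocol

One class is declared positive, the rest jointly negative. True positives
are positives called positive; false negatives are positives called
anything else **or rejected**; false positives are negatives called
positive; true negatives are all remaining negatives, including
negative-to-negative confusions and rejected negatives. These rules make
$tp+fn$ and $fp+tn$ invariant to the rejection threshold, which is what
gives the ROC sweep (thresholds 0.30 to 0.99 in steps of 0.01, 70 points,
posteriors computed once and re-thresholded) its monotone TPR/FPR and a
non-decreasing unclassified fraction. Cross-validation is stratified
(an undocumented point in the protocol this package follows; stratification
is the reproducible default) with a seeded, class-balanced round-robin
assignment whose dealing position rolls across classes so leave-one-out
works; with threshold 0 nothing is rejected and accuracy is plain argmax
accuracy.

## Sequence features

Small regulatory RNAs in the target length range (roughly 15–40 nt) lack
strong secondary structure, so features are purely compositional: for each
$k = 1..5$ all length-$k$ windows over $\{A,C,G,U\}$ are counted and
normalized **per k** (each block its own simplex, the natural reading of
per-type normalization and what keeps blocks comparable across $k$),
yielding $4+16+64+256+1024 = 1364$ dimensions. Windows containing N are
skipped with the denominator adjusted, preserving the simplex property; a
block with no valid window is all zeros. T and U spellings are equivalent
after canonicalization. Background ("other ncRNA") sequences longer than
20 nt are represented by one uniformly random 20-nt fragment — a length
both a miRNA and a piRNA could have — drawn deterministically from the
seed and the record id so results are independent of record order; miRNA
and piRNA sequences are used whole. Class balancing downsamples to the
minority count. Redundancy reduction of real sequence sets (e.g. CD-HIT at
80% identity) is recommended upstream and is outside this package.

## Synthetic fixtures and what they establish

The generators are pure functions of seed and parameters:

* `gaussian_blobs` — isotropic Gaussian classes around given centers. The
  package's end-to-end checks use three classes, 100 points per class, unit
  variance, centers 10 standard deviations apart: an easy, unambiguous
  task whose purpose is falsifying the machinery (a correct implementation
  must be near-perfect; any accuracy loss flags a defect), not estimating
  realistic performance.
* `consistent_gbt_observations` — binary outputs constructed to satisfy the
  Bradley-Terry model exactly for a known $p$, the recovery oracle for the
  iterative decoder (recovery to $10^{-3}$ within the 1000-sweep cap is
  verified across $K \in \{3, 5, 10\}$).
* `synthetic_sequences` — per-class first-order (dinucleotide) Markov
  chains over $\{A,C,G,U\}$ whose transition tables are log-normal
  perturbations of uniform, scaled by `bias_strength`; lengths uniform on
  15–40 nt, the observed range of the target RNA classes. Markov chains
  rather than i.i.d. bases were chosen deliberately so that $k>1$ features
  carry signal and the full 1364-dimensional featurizer is exercised
  meaningfully. Zero bias makes the classes identical, pinning chance-level
  accuracy; strong bias pins high accuracy.

None of these fixtures mimic real small-RNA biology — no seed motifs, no 1U
bias, no evolutionary redundancy. Passing tests therefore establish that
the algorithms are implemented correctly and behave as their theory
predicts, not that any particular accuracy will be achieved on real
mirBase/NONCODE-scale data, where class overlap (mature miRNA versus other
ncRNA fragments especially) is far harsher.

## Problem sizes and determinism

The shipped tests and the reproduction script run at deliberately desk
scale: blob tasks with 300 training and 300 test points, 1000-instance
decoder-oracle sweeps, 300 Bradley-Terry recovery problems, 120-sequence
featurization runs, and 10-fold cross-validation on the 150-instance iris
data. These sizes were chosen so the whole suite is comfortable on a single
CPU while leaving every code path load-bearing. Everything stochastic —
clustering initializations, candidate code pools, fixture draws, fold
splits — flows from explicit integer seeds, and training with the same
seed is byte-identical on disk (models serialize to JSON with 17
significant digits, which round-trips IEEE doubles exactly).

## Known limitations

* Only the Gaussian kernel is implemented (the kernel field is a hook).
* The direct multiclass (softmax) formulation is deliberately absent: its
  training cost scales cubically with the class count, which is the reason
  the decomposition approach exists.
* The historical relevance-units solver is reconstructed, not reproduced;
  absolute weight values may differ from other implementations even where
  decisions agree.
* The naive decoder's independence assumption makes it unreliable under
  random dense/sparse codes; use the Bradley-Terry decoder there.
* No AUC summaries are computed; the ROC table is the deliverable and
  plotting is left to the user.
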