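---
title: "Methods: a block-sparse Bayesian fuzzy classifier for RNA modification sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a block-sparse Bayesian fuzzy classifier for RNA modification sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsblfs)
```

## The problem

N6-methyladenosine (m6A) and related modifications (m5C) are deposited at
specific positions of mRNA, most mammalian m6A sites falling inside the
DRACH consensus (D = A/G/U, R = A/G, H = A/C/U), with GGACA its most common
realization. Sequence-based predictors classify a fixed-length window
(conventionally 41 nt, centred on the candidate adenosine) as modified or
unmodified. `bsblfs` implements one such classifier: a first-order
Takagi-Sugeno-Kang (TSK) fuzzy system over position-specific k-mer
propensity features, whose rule consequents are learned by block-sparse
Bayesian learning (BSBL) instead of a hand-tuned ridge penalty.

## Feature encoding: position-specific k-mer propensities

For window length $L$ and k-mer order $k$ (default $L = 41$, $k = 5$), the
training split defines, for each of the $4^k$ k-mers $m$ and each start
position $j \in 1..(L-k+1)$, the relative frequencies $F^+(m, j)$ and
$F^-(m, j)$ of $m$ at $j$ within the positive and negative class. A window
$s$ is encoded as the $(L-k+1)$-dimensional vector

$$z_j(s) = F^+(s_{j..j+k-1},\, j) - F^-(s_{j..j+k-1},\, j),$$

37 features for the defaults. Each column of $F^\pm$ is a probability
distribution over k-mers, so each propensity column sums to zero. The
difference form is the package default because the discriminative signal in
this family of encoders is the positive/negative contrast; the
positive-frequency-only variant is available via `psnpMode = "positive"`
rather than guessed to be canonical. A k-mer unseen in both classes scores
exactly 0; an optional additive pseudocount (default 0) smooths rare
k-mers. Positions are reported 1-based inclusive everywhere (the GGACA
motif of a 41-nt window occupies positions 19–23; the site adenosine is
position 21). Internally, matrices are indexed 1-based as usual in R.

The table is always built from the training split only. The
cross-validation driver rebuilds it inside every fold, and a test asserts
that corrupting held-out sequences cannot change the trained table.

## The TSK fuzzy system

With $K$ rules (default 25), rule $k$ carries a Gaussian membership per
feature,

$$\mu_{A_j^k}(x_j) = \exp\!\left(-\frac{(x_j - c_j^k)^2}{\delta_j^k}\right),$$

with no factor $\tfrac12$ and $\delta$ (a variance-scale, not a standard
deviation) in the denominator — the membership is implemented exactly in
this form. Rule memberships multiply across features (product t-norm) and
normalize across rules to firing strengths $\tilde\mu_k(x)$. The model
output is the firing-strength-weighted sum of affine rule consequents,
equivalently the inner product $x_g \cdot p$ of the lifted design row

$$x_g = \big(\tilde\mu_1(x)(1, x),\; \ldots,\; \tilde\mu_K(x)(1, x)\big)
\in \mathbb{R}^{(1+d)K}.$$

Products of up to $d = 37$ Gaussian factors underflow easily, so firing
strengths are accumulated in the log domain with per-row max subtraction;
rows of the firing matrix then sum to 1 by construction and a 0/0
normalization cannot occur. This also removes any need for tie-breaking.

Antecedents come from fuzzy c-means (FCM) on the training features.
The FCM iteration uses the standard exponentiated memberships
($u_{ik}^m$ in the centre update), while the antecedent estimates use the
raw memberships:

$$c_j^k = \frac{\sum_i u_{ik} x_{ij}}{\sum_i u_{ik}}, \qquad
\delta_j^k = h\,\frac{\sum_i u_{ik} (x_{ij}-c_j^k)^2}{\sum_i u_{ik}},$$

the form in which the antecedent estimates are specified for this model
family. Widths are floored at $10^{-8}\widehat{\mathrm{var}}_j + 10^{-12}$
so a cluster collapsing onto a constant feature cannot produce a zero
width. FCM initializes centres as $K$ distinct training rows drawn under
the configured seed, stops when the maximum centre shift falls below
$10^{-6}$ (at most 300 iterations), and is bit-reproducible given the seed.

Choices left open by the model family, decided once here: $K = 25$ rules (a
mid-range rule count for TSK systems on ~40-dimensional inputs; every
report echoes the configured $K$), fuzziness $m = 2$ (the standard FCM
exponent) and width coefficient $h = 1$. All three are configurable.

## Block-sparse Bayesian learning of the consequents

Stacking the per-rule consequents $p^k \in \mathbb{R}^{1+d}$ gives
$p \in \mathbb{R}^{(1+d)K}$ with a natural block structure of $M = K$
blocks — one per rule, the only block map consistent with the per-rule
stacking; all-singleton and custom maps are supported for the ablations.
The prior is $p_i \sim \mathcal{N}(0, \gamma_i B_i)$ per block with
nonnegative scales $\gamma_i$ and intra-block correlation matrices $B_i$;
labels are regressed as $y \sim \mathcal{N}(X_g p, \beta^{-1} I)$ with
$y_i \in \{+1, -1\}$. The posterior is Gaussian with

$$\Sigma = (\Gamma^{-1} + \beta X_g^\top X_g)^{-1}, \qquad
\mu = \beta\, \Sigma X_g^\top y,$$

and hyperparameters are estimated by type-II maximum likelihood,
minimizing $\mathcal{L} = \log|C| + y^\top C^{-1} y$ with
$C = \beta^{-1} I + X_g \Gamma X_g^\top$. The EM updates are

$$\gamma_i = \frac{1}{d_i}\mathrm{Tr}\!\left[B_i^{-1}(\Sigma_i + \mu_i\mu_i^\top)\right],
\qquad B_i = \frac{\Sigma_i + \mu_i\mu_i^\top}{\gamma_i}, \qquad
\beta = \frac{N}{\|y - X_g\mu\|^2 + \mathrm{Tr}[\Sigma X_g^\top X_g]}.$$

Numerical and structural choices:

* **Initialization.** $\gamma_i = 1$ for all blocks, $B_i = I$, and
  $\beta_0 = 0.01\,\|y\|^2$ (the literal published rule for this model;
  for $\pm 1$ labels this is $0.01N$). Because that rule degenerates to
  $\beta_0 = 0$ when $y = 0$, a fallback of 1 keeps the degenerate case
  well defined. The more conventional precision-style rule
  $\beta_0 = 1/(0.01\,\mathrm{var}(y))$ is selectable via
  `betaInitRule = "noise-variance"`.
* **Correlation constraint.** The raw $B_i$ update estimates a full
  $d_i \times d_i$ matrix from a single block's statistics and overfits.
  By default the raw updates of all active blocks are diagonal-normalized
  and pooled; the intra-block correlation coefficient $r$ is the ratio of
  the pooled first off-diagonal mean to the pooled diagonal mean, clipped
  to $(-0.99, 0.99)$, and every $B_i$ is set to the first-order
  autoregressive matrix $\mathrm{Toeplitz}(1, r, r^2, \ldots)$ — the
  standard regularization of $B$ in the BSBL literature, reconstructing a
  quantity the model family references but does not define. `"none"`
  reproduces the literal raw update, `"unit-scaled"` only fixes the scale.
* **Pruning.** Blocks with $\gamma_i < 10^{-4}\max_j \gamma_j$ are clamped
  to zero and leave the working set, keeping $\Gamma^{-1}$ well defined.
  Pruning is a numerical device; *recovered support* for recovery
  experiments is reported by the separate rule
  $\gamma_i > 10^{-2}\max_j\gamma_j$ (`recoveredSupport()`), since the EM
  equilibrium can hold inactive blocks at a small nonzero noise floor.
* **Convergence.** $\|\gamma^{new}-\gamma\|/\|\gamma\| \le \eta$ with
  $\eta = 10^{-4}$ (the criterion's threshold is not fixed by the model
  family; $10^{-4}$ balances accuracy against the cost of late, nearly
  stationary iterations), capped at 500 iterations; non-convergence is
  flagged on the returned model, not an error.
* **Linear algebra.** The posterior is computed in the primal form when
  the active dimension is at most $N$ and through the dual (Woodbury)
  factorization of $C$ otherwise; the two agree to $10^{-8}$ and both are
  exposed for testing. Inside the EM loop the cost is evaluated through
  the determinant identity
  $\log|C| = -N\log\beta + \log|\Gamma| + \log|\Sigma^{-1}|$ and
  $y^\top C^{-1}y = \beta\, y^\top(y - X_g\mu)$, which is exact and avoids
  forming $C$; the public `bsblCost()` factorizes $C$ explicitly and
  serves as the oracle. All PD factorizations route through a Cholesky
  with escalating relative jitter (starting at $10^{-10}$), logged when
  triggered.
* **$\beta$ guard.** The denominator of the $\beta$ update,
  $\|y - X_g\mu\|^2 + \mathrm{Tr}[\Sigma X_g^\top X_g]$, is nonnegative in
  exact arithmetic, but at a near-perfect fit cancellation in the
  dual-form $\Sigma$ can drive the trace term slightly negative. The trace
  is clamped at 0 and the denominator floored at $10^{-12}N$, capping
  $\beta$ at $10^{12}$.
* **Monotonicity.** With the published $\beta$ update the cost is not
  guaranteed monotone; the trace is recorded and increases beyond a
  $10^{-6}$ relative threshold are logged rather than asserted. In
  practice the observed increases are tiny and late in the run.
* **No penalty constant.** `fitBsbl()` deliberately exposes no
  regularization constant beyond the numerical jitter: the point of the
  Bayesian treatment is that the effective penalty is learned.

The plain sparse-Bayesian ablation (`fitSbl()`) is the same engine with
every coefficient its own block ($d_i = 1$, $B_i = 1$); running the block
engine with an all-singleton map is bit-identical to it. The classical TSK
baseline (`fitLs()`) is ridge least squares
$p = (X^\top X + \lambda I)^{-1}X^\top y$ with $\lambda = 1$ by default — a
neutral mid-range penalty for the ablation, deliberately not tuned per
dataset, which is exactly the weakness the Bayesian learners address.

**Prediction.** The score is $x_g\cdot\mu$; the predictive standard
deviation is $\sqrt{x_g \Sigma x_g^\top + 1/\beta}$; the positive-class
probability is the probit transform $\Phi(\mathrm{score}/\mathrm{sd})$,
which follows from the Gaussian predictive distribution (an
interpretation: the model is a regression on $\pm1$ labels, and this is
the natural monotone map of its predictive mean to $(0,1)$). The decision
label is $+1$ iff score $> 0$; an exact 0 maps to $-1$. The ridge baseline
carries no posterior covariance, so its probability is $\Phi(\mathrm{score})$
— monotone in the score, hence AUC-equivalent.

## Evaluation protocol

Stratified 5-fold cross-validation with a seeded shuffle; every
training-split quantity (propensity table, FCM, antecedents, fit) is
recomputed per fold. Summary metrics are unweighted fold means (macro) —
the aggregation used for single-number-per-dataset reports — with a pooled
(micro) variant behind a flag. Metrics: SN, SP, ACC, MCC (0 when a
denominator factor vanishes), and rank-statistic AUC with half credit for
ties, which equals the trapezoidal ROC area. On balanced data
ACC = (SN + SP)/2 identically. Cross-dataset evaluation trains the full
pipeline on one dataset and scores another once; a matrix runner iterates
all ordered pairs into a long-format table.

## What the synthetic generators emulate

`genBlockSparse()` samples the generative model the block prior assumes:
i.i.d. Gaussian design, a chosen number of active blocks with
Toeplitz-correlated coefficients, and noise rescaled so the realized SNR
matches the request exactly. It grounds the support-recovery and ablation
experiments in a known truth.

`genMotifDataset()` emulates the statistical structure reported for real
m6A benchmarks: balanced classes of 41-nt windows, an adenosine at
position 21 in both classes (negatives are unmodified adenosine sites), a
GGACA motif across positions 19–23 of positives with per-position
fidelity, GC-rich positive flanks versus AU-rich negative flanks
(background P(G) = P(C) = gc/2, P(A) = P(U) = (1-gc)/2). The shipped
presets are `strong` (fidelity 0.95, GC 0.6 vs 0.35), `moderate` (0.8,
0.5 vs 0.42) and `null` (no motif, identical background — no class signal
by construction). These values were fixed once from the reported
qualitative contrasts, before any end-to-end measurement, and are not
revisited.

What the generator does *not* emulate: positional dependence beyond the
single motif, transcript context, secondary structure, sequence redundancy
(real benchmarks are CD-HIT-filtered upstream), and class imbalance.
Passing the synthetic end-to-end checks therefore demonstrates that the
pipeline recovers the kind of positional signal these benchmarks carry,
not that it attains any particular accuracy on the real datasets.

## Problem sizes used by the test suite

The packaged checks run the support-recovery battery at $N = 150$,
$M = 20$ blocks of 4, 3 active, $r = 0.9$, 25 dB over 50 seeds; the
ablation ordering on the same generator with a 150/150 train/test split
over 20 seeds; and the end-to-end cross-validation at 1000 + 1000
sequences. These sizes were chosen as the smallest at which the studied
effects are stable across seeds.

## Known limitations

* The fuzzy design is dense; with $K = 25$ and $d = 37$ it has 950
  columns, and training cost is dominated by repeated $O(D_a^3)$ or
  $O(N^3)$ factorizations until pruning shrinks the active set. Datasets
  of tens of thousands of windows are feasible but slow in this pure-R
  implementation.
* The probability output is an interpretation of the Gaussian predictive
  distribution of a label regression, not a calibrated class posterior.
* FCM is a local method; different seeds can place rules differently.
  Reports echo the seed, and the default configuration is
  bit-reproducible.
* The default $K = 25$ is sized for training sets of a thousand windows
  or more per class. On much smaller training splits (a few hundred
  windows against the 950-column design) the evidence optimization prunes
  most rules, and the survivors can leave one class without a live rule:
  ranking (AUC) stays informative but the threshold-0 decision degrades.
  Reduce `rules` in proportion to the data in that regime.
* With no signal (label-permuted or null data) the evidence optimization
  shrinks all blocks slowly and typically exhausts `maxIter`; this is
  flagged as non-convergence and is benign — scores hover near 0.
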