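---
title: "Score-based causal discovery by reinforcement learning, with inverse-entropy edge strengths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-based causal discovery by reinforcement learning, with inverse-entropy edge strengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlcausal)
```

## The problem

Given an $m \times d$ table of continuous observations — epidemiological
risk factors measured on $m$ subjects, say — we want a directed acyclic
graph (DAG) over the $d$ variables that explains the data well, together
with a per-edge weight expressing how strong each putative causal relation
is. The package does this in two stages:

1. **Structure search.** A stochastic policy over directed graphs is trained
   by actor-critic reinforcement learning to maximize a reward built from
   the Bayesian information criterion (BIC) and two acyclicity penalties;
   the maximum-reward DAG is the discovered skeleton-with-orientation.
2. **Strength annotation.** Each discovered edge gets an
   inverse-information-entropy (IIE) strength, the reciprocal of the
   absolute difference of the two variables' estimated differential
   entropies; edges with strength below 0.5 are pruned as redundant.

## Stage 1: the model

### Policy network

Each variable is represented by $n_s$ of its observed values (rows drawn
uniformly without replacement, fresh at every iteration), mapped by a shared
linear layer to a $d_{model}$-dimensional embedding. A stack of identical
encoding layers — multi-head self-attention, then a position-wise
feedforward network, each wrapped as $\mathrm{LayerNorm}(x +
\mathrm{Sublayer}(x))$ — turns the $d$ embeddings into $d$ summary vectors
$enc_1, \dots, enc_d$. There is no positional encoding: variables are an
unordered set, and the encoder is permutation-equivariant (a property the
test suite checks numerically).

A single-layer decoder scores every ordered pair,
$$ g_{ij} = u^\top \tanh(W_1\, enc_i + W_2\, enc_j), $$
and an adjacency matrix is sampled entrywise as
$M_{ij} \sim \mathrm{Bernoulli}(\sigma(g_{ij}))$ with the diagonal forced to
zero (no self-loops).

### Scoring

For continuous data we use the Gaussian linear family: each node is
regressed on its parents by least squares with an intercept, and its
node-local score is $m \log(\mathrm{RSS}/m) + k \log m$ with $k$ the number
of fitted mean parameters. The graph's BIC is the sum of node-local terms
(the score is decomposable, so a per-run cache keyed by (node, parent set)
makes repeated scoring cheap). Acyclicity is measured by
$h(A) = \mathrm{trace}(e^A) - d$, which is zero exactly on DAGs, and the
reward of a sampled graph is
$$ \mathrm{reward} = -\left[ S_{BIC}(\mathcal{G})
   + \lambda_1 I(\mathcal{G} \notin \mathrm{DAGs})
   + \lambda_2 h(A) \right]. $$

### Training

Each iteration samples a batch of graphs from the current edge
probabilities, scores them, and performs two Adam updates: the critic (a
two-layer tanh network on the mean-pooled encoder output) minimizes the mean
squared error between its predicted and the realized rewards, and the
policy ascends advantage-weighted log-probability gradients, with advantage
= reward − critic prediction. All gradients are exact analytic
backpropagation through the decoder, the attention stack and the embedding
map; the implementation is plain dense matrix algebra, which is entirely
adequate at these problem sizes ($d \le$ a few dozen).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_layers`, `d_model`, `n_heads`, `d_ff` | 6, 512, 8, 2048 | encoder size; reduced (2, 16, 4, 64) for small problems and all tests |
| `n_s` | 64 | rows sampled per iteration to represent each variable |
| `iterations`, `graphs_per_iteration` | 10000, 32 | search budget |
| `learning_rate` | 2e-3 | Adam step for policy and critic |
| `lambda1`, `lambda2` | 1, 10 | DAG-indicator and $h(A)$ penalty weights, on the normalized-BIC scale |
| `entropy_weight` | 0.2 | Bernoulli entropy bonus on the policy |
| `threshold` | 0.5 | minimum IIE strength an edge must reach to survive |

Three numerical choices deserve explanation.

**Score normalization.** Raw BIC values are dataset-scale; with them, no
single $(\lambda_1, \lambda_2)$ default is portable. By default the trainer
affinely rescales BIC online to $[-1, 0]$ using the running min/max before
it enters the reward, so the acyclicity penalties are commensurate across
datasets. This makes the reward nonstationary, which interacts with "keep
the maximum-reward graph": we therefore log every distinct graph scored
during the run (raw BIC, $h$, DAG flag) and select the best under the
*final* normalization constants. The selection is deterministic, and the
reported best reward equals the maximum over all scored graphs by
construction.

**Entropy regularization.** With a shared decoder, the early phase of
training — where dense, heavily penalized cyclic graphs dominate the batch
— pushes *every* edge probability down in lockstep, and a collapsed policy
(all probabilities near 0) samples no informative graphs and cannot recover.
A Bernoulli entropy bonus (weight 0.2) on the policy objective keeps edge
probabilities away from the degenerate corners, which maintains exploration
throughout the run and lets pair-specific preferences emerge. Per-batch
advantage scaling (dividing by the batch standard deviation) keeps the
policy step size meaningful even late in training when most sampled graphs
score similarly. Both are standard actor-critic devices; setting
`entropy_weight = 0` recovers the plain update.

**RSS floor.** A deterministic parent-child relation drives the residual
sum of squares to zero and the node score to $-\infty$; RSS is clamped
below at $10^{-8} m$, which keeps every reward finite without affecting the
ranking of non-degenerate graphs.

## Stage 2: entropies and strengths

The differential entropy of a variable is estimated from adjacent spacings
of its order statistics:
$$ \hat S(X) = \psi(n) - \psi(1)
   + \frac{1}{n-1} \sum_{i=1}^{n-1} \log |x_{(i+1)} - x_{(i)}|, $$
with $\psi$ the digamma function, in natural log (the digamma form is only
consistent in nats). The estimator is affine-equivariant,
$\hat S(aX+b) = \hat S(X) + \log|a|$, exact up to floating point.

Repeated values create zero spacings, on which the estimator is undefined;
real risk-factor tables (zero-coded measurements, integer ages) are full of
them. The default policy drops zero spacings from the sum and averages over
the remaining count; an `epsilon` policy (floor spacings at $10^{-12}$) is
available for comparison but drags estimates far down when ties are common.

The IIE strength of an edge $X_i \to X_j$ is $1/|\hat S(X_j) - \hat
S(X_i)|$, capped at $10^{12}$ when the entropies coincide. It is symmetric —
it weighs an edge but cannot orient it; orientation comes from stage 1
only. Strengths are computed on the *normalized* data by the pipeline
(min-max per column), so every variable lives on $[0,1]$ and entropy
differences are dimension-free; raw-data strengths are available by passing
raw columns to `iie_strength()`. Edges with strength $< 0.5$ are removed;
exactly 0.5 is kept.

**Why min-max normalization?** The normalization applied in step 1 is not
named by the method's description; we use per-column min-max to $[0,1]$
because the spacing estimator's affine equivariance means any per-column
affine map shifts entropies by a constant, and mapping every variable to a
common bounded support makes entropy *differences* — hence strengths —
comparable across pairs. A z-score alternative is exposed
(`normalization = "zscore"`). Published strength values for this family of
methods depend on both the normalization and the tie policy, neither of
which is standardized, so cross-implementation numerical agreement on real
tables should not be expected to the last digit.

## The synthetic benchmark

`random_dag(d, edge_prob)` draws a uniformly-permuted triangular random
graph; `ground_truth_sem()` puts weights $\pm U[0.5, 2]$ on the edges
(bounded away from zero, so effects are detectable) with unit Gaussian
noise; `sample_linear_sem()` generates observations in topological order.
This emulates the linear-Gaussian world in which BIC is the textbook score.
It does **not** emulate nonlinear effects, latent confounders, selection
bias, heavy ties, or discreteness — passing the synthetic suite therefore
shows the search and scoring machinery work, not that real epidemiological
tables will yield textbook structures. `shd()` counts
insertions + deletions + reversals, a reversal costing 1.

Problem sizes used by the test suite and the acceptance script — a d = 3
chain (m = 500, 500 iterations) checked against the exhaustive 25-DAG
optimum, and a d = 5 random DAG (edge probability 0.4, m = 1000, 2000
iterations, reduced network) checked by structural Hamming distance — were
chosen so an exact exhaustive oracle exists and a complete run takes
minutes on one CPU.

## Known limitations

- BIC identifies linear-Gaussian structure only up to Markov equivalence;
  on equivalence classes the search may return a score-tied reorientation
  of the true graph (SHD counts these as 1 each).
- The IIE strength depends only on marginal entropies, so it cannot
  distinguish which of two equal-entropy-gap edges is "more causal", and it
  is blind to orientation.
- The RL search is a stochastic optimizer with no optimality certificate;
  for $d \le 5$, `exhaustive_search()` gives the exact answer and should be
  preferred.
- Entropy estimation assumes continuous marginals; heavily tied columns are
  handled by the tie policy but estimated poorly.
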