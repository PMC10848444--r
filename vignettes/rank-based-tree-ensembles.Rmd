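---
title: "Rank-based tree ensembles: model, design choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based tree ensembles: model, design choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Gene expression is measured on incompatible scales: microarray
intensities, RNA-seq counts, FPKM, each with its own normalisation.  A
classifier trained on one platform usually cannot score a single sample
from another, because any cross-sample normalisation re-introduces the
very batch structure it was meant to remove.  A *single-sample predictor*
avoids this by using only quantities computable inside one profile.  The
simplest such quantity is the order of two genes: the indicator
$\mathbb{1}\{x_i \le x_j\}$ is unchanged by any strictly increasing
transform of the sample's values, which is exactly what a platform change
is (to a good approximation).

This package builds decision trees whose **every split is such a pair
comparison**.  At a node with class counts $n_k$ ($n = \sum_k n_k$), a
candidate split on the pair $(i, j)$ sends samples with
$x_i \le x_j$ left and the rest right, and is scored by

$$g = \frac{1}{n}\sum_{k=1}^{K}\frac{n_{k,l}^2}{n_l}
    + \frac{1}{n}\sum_{k=1}^{K}\frac{(n_k - n_{k,l})^2}{n - n_l},$$

where $n_{k,l}$ counts class $k$ in the left daughter.  Maximising $g$ is
algebraically identical to minimising the sample-weighted Gini impurity
$\phi(p) = 1 - \sum_k p_k^2$ of the daughters ($g$ equals one minus that
weighted impurity; the test suite checks the identity to $10^{-12}$ on
random count configurations).  A tree of one split is exactly a
top-scoring-pair (TSP) classifier; deeper trees are conjunctions of
reversals, which is where the additional modelling power comes from.

Two ensembles tame the variance of single trees:

* **Random rank forest** (`rank_forest()`): each of $M$ trees is grown on
  an independent class-balanced bootstrap, with a fresh draw of $Q'$
  candidate genes at every node (all $Q'(Q'-1)/2$ unordered pairs within
  the draw are scored).  The forest probability of class $k$ is the vote
  fraction $\hat p_k(x) = M^{-1}\sum_m \mathbb{1}\{h_m(x) = k\}$.  The
  samples left out of each bootstrap (about $1 - 0.632 = 0.368$ of them)
  provide an out-of-bag (OOB) error estimate with no extra
  cross-validation.

* **LogitBoost boosting** (`rank_boost()`): shallow rank-pair *regression*
  trees are fitted sequentially to the working response
  $z = 2y/(1 + e^{2yF})$, the negative gradient of the cost
  $C(y, F) = \log(1 + e^{-2yF})$, $y \in \{-1, +1\}$.  Terminal values are
  the one-step Newton coefficients
  $\gamma_s = \sum z \,/\, \sum |z|(2 - |z|)$ and the score is updated
  with shrinkage $\lambda$.  Probabilities are
  $1/(1 + e^{-2F_M})$; $K \ge 3$ classes are handled by $K$
  one-against-all models with renormalised probabilities.

On top of the ensembles sit three analysis layers: if–then **rules**
harvested from forest paths (`extract_rules()`, `select_rules()`),
**gene-pair permutation importance** (`pair_importance()`), and a
two-stage **dimension reduction** (`reduce_dimension()`).

## Tunable parameters

| parameter | default | meaning and guidance |
|---|---|---|
| `n_trees` (M) | 500 | trees / boosting iterations.  Accuracy plateaus early; 250 is usually indistinguishable from 1000 (asserted on synthetic data by the test suite).  More trees never overfit the forest, they only cost time. |
| `max_depth` | unlimited (forest), 3 (boosting) | forests rely on averaging deep trees; boosting on combining weak, shallow ones. |
| `min_node_size` | 1 (forest), 5 (boosting) | a node with fewer than `2 * min_node_size` samples is not split. |
| `n_candidate_genes` (Q') | `ceiling(sqrt(P))` | genes drawn per node; performance is flat in Q' when Q' ≪ P.  The same default is used for boosting (candidate subsampling matters little there, and the randomisation decorrelates consecutive trees). |
| `lambda` | 0.1 | boosting shrinkage in (0, 1]; accuracy is robust across 0.01–0.3 (asserted synthetically), so cross-validate only if squeezing the last percent. |
| `gamma_clip` | 4 | symmetric bound on node coefficients; the closed form has a near-zero denominator at near-pure nodes. |
| `sampling` | `"bootstrap"` | per-class draws of `ceiling(N/K)` with replacement; `"subsample"` draws without replacement (capped at the class size). |

## Ties and zeros

The paper-level theory assumes continuous values, where ties are
measure-zero.  Real data, especially zero-inflated single-cell counts,
tie often.  The package uses one fixed convention — **ties route left**
($x_i \le x_j$) — so predictions are deterministic and reproducible; the
cost is that blocks of tied values carry no ranking information, which
degrades accuracy when zeros are abundant.  `break_ties()` implements the
standard remedy, a seeded uniform jitter below the smallest informative
gap.  The generator's `tie_rate` argument exists to exercise exactly this
failure mode.

## Numerical and algorithmic choices

* **Strict improvement**: a node is split only if the best candidate's
  $g$ exceeds the no-split value by more than $10^{-12}$; otherwise it is
  terminal.  Score ties between pairs break to the lexicographically
  smallest $(i, j)$, so fits are bit-reproducible at a fixed seed.
* **One seed**: every fitter takes a single integer `seed` from which all
  bootstrap, candidate-draw and stage randomness flows; fits with equal
  seeds are identical objects.
* **Pair importance sign**: importance is reported as (loss after
  swapping columns $i$ and $j$ in the OOB data) − (baseline OOB loss), so
  informative pairs are positive, matching the universal "bigger = more
  important" convention.  "Permutation" is implemented as the column
  swap, the operational definition of reversing the $i$–$j$ relationship
  in every tree; the Brier score $(1/K)\sum_k(\mathbb{1}\{Y=k\}-\hat
  p_k)^2$ is the default loss.  A pair used by no tree has importance
  exactly 0, by construction and by test.
* **Gamma via one Newton step**: the closed form for $\gamma_s$ is a
  single Newton step from 0, not the exact minimiser; its error is
  quadratic in the node optimum.  The tests therefore compare it with a
  golden-section oracle on near-converged nodes (optimum within 0.02 of
  zero), where agreement to $10^{-4}$ holds.
* **Boosting probability**: the final score is converted as
  $P(Y = +1 \mid x) = 1/(1 + e^{-2F_M(x)})$, reading the cost's
  probability formula as the probability of the observed label.
* **One-against-all decoding**: per-class probabilities are simply
  renormalised to sum to one; only the encoding is canonical, and the
  simplest decoding keeps the model auditable.
* **Rule scoring**: each forest path conjunction is scored on the source
  tree's OOB samples that satisfy it.  Ranking uses a Laplace-smoothed
  error $(\text{wrong} + 1)/(\text{support} + 2)$ rather than the raw
  rate: under label noise the best achievable rule error equals the noise
  rate, so raw-error ranking systematically prefers narrow
  zero-measured-error leaves over well-supported honest rules.  The raw
  OOB error is still reported per rule.  Remaining ties break by support,
  then rule length, then source order; duplicate condition sets collapse.
* **Rule length**: full-depth leaves of a memorising forest are long,
  narrow conjunctions.  `extract_rules(fit, max_length = 3)` truncates
  paths at depth 3, producing short rules whose error estimates rest on
  tens of OOB samples; this is the recommended setting for
  interpretation, and five such rules come within a few accuracy points
  of the full forest on the synthetic benchmark.  Rules are for
  interpretation; the forest remains the predictor of record.
* **Gene/pair selection thresholds**: `reduce_dimension()` keeps genes
  and pairs with importance strictly above 0 (configurable).  Noise pairs
  have importance jittered around zero, so roughly half of them are
  weakly positive and gene-stage retention is liberal; raising
  `threshold` trades recall for sparsity.  Degenerate outcomes (nothing
  positive; a single gene) fall back with warnings rather than failing.

## What the synthetic generator does and does not emulate

`simulate_rank_data()` produces data whose labels are functions of
planted pair-order relations, so ground truth is known exactly:

* Each planted pair shares a **baseline expression level**, and baselines
  are spread over orders of magnitude across pairs (as real genes are),
  so the class signal lives in within-pair order, not in cross-pair
  comparisons.  Baselines are deterministic in the gene index, making
  independently simulated datasets draws from one population.
* Class 1 satisfies all planted relations; class 2 satisfies each with
  probability `null_agreement = 0.10` (conditioned on not satisfying
  all), with a balanced rotation deciding which — the *relative
  expression reversal* premise of TSP classification, with every planted
  relation carrying equal signal.  No single pair separates the classes;
  conjunctions do.
* Label noise reassigns a fixed, class-stratified fraction
  (`flip_noise`), so the Bayes accuracy is $1 - $ `flip_noise` and
  two-class balance is exact.
* `distortion = "monotone"` or `"platform"` applies strictly increasing
  per-sample maps (log-like vs power-like blocks), which change every
  value and no pair indicator — the cross-platform setting in its pure
  form.

`standard_benchmark()` freezes the canonical instance: 200 samples
(100/100), 50 genes, 5 planted pairs on genes 1–10, 5% flips, seed
20240207.

What the generator deliberately does **not** emulate: realistic marginal
distributions of microarray or RNA-seq data, gene–gene correlation
networks, batch structure beyond monotone maps, or partially informative
("weak") pairs.  Passing tests on this generator demonstrates that the
algorithms recover planted rank structure under label noise and monotone
distortion; it does not certify accuracy levels on any real cohort.

## Problem sizes used by the tests

Unit tests run at small sizes (tens of samples, 8–30 genes, 10–150
trees).  The end-to-end checks use the standard benchmark with 500-tree
forests, a 400-sample held-out draw from the same population, 200
boosting iterations, a 10,000-replicate bootstrap experiment at
$n = 1000$, and forests of 250 vs 1000 trees for the robustness
comparison — the sizes at which the measured quantities (OOB accuracy
near 0.95, recall of all planted pairs in the top importance ranks,
five-rule accuracy within 0.05 of the forest) are stable across seeds.

## Known limitations

* All $O(P^2)$ pair candidates are only ever touched through per-node
  subsampling; for very large $P$ the two-stage reduction is the intended
  route, and its first stage is itself a full ensemble fit (a filter
  pre-screen is out of scope by design).
* Boosting handles multi-class problems one-against-all, so $K$ models
  are fitted; forests handle $K$ classes in one model and are preferable
  for many-class or large problems.
* Missing values are rejected, not imputed; there are no surrogate
  splits.
* Heavy zero-inflation erodes the method's premise (see *Ties and
  zeros*).

## A worked example

```{r, eval = FALSE}
library(pairtree)

sim <- standard_benchmark()
fit <- rank_forest(sim$data, n_trees = 500, seed = 1)
fit                          # OOB error and confusion matrix

vi <- pair_importance(fit)   # planted pairs surface at the top
head(vi, 5)

rules <- select_rules(extract_rules(fit, max_length = 3), 5)
rules                        # five human-readable reversal rules

red <- reduce_dimension(sim$data, n_trees = 300, seed = 2)
red$report                   # genes and pairs retained
```
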