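---
title: "Model and methods behind gbhc"
author: "gbhc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind gbhc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbhc)
```

## The clustering model

`gbhc` clusters the rows of an expression matrix by Bayesian hypothesis
testing instead of a distance metric. The generative picture is a Dirichlet
process mixture (DPM): each cluster is one mixture component, and within a
component every dimension $g$ is an independent Gaussian with unknown mean
$\mu_g$ and precision $\tau_g$,

$$x_{ig} \mid \mu_g, \tau_g \sim \mathcal N(\mu_g, \tau_g^{-1}), \qquad
  (\mu_g, \tau_g) \sim \text{NormalGamma}(m = 0,\, c,\, a,\, b).$$

The normal-gamma prior is conjugate, so the marginal likelihood of a cluster
$D_k$ — the probability of its data with the unknown mean and precision
integrated out — is available in closed form. With $n$ observations whose
per-dimension mean is $\bar x_g$ and sum of squared deviations is
$s_g$, the posterior hyperparameters are

$$c_n = c + n, \qquad a_n = a + n/2, \qquad
  b_{n,g} = b + \tfrac{1}{2} s_g + \frac{c\, n\, \bar x_g^2}{2 (c + n)},$$

and the per-dimension log marginal is

$$\log p(x_g) = \log\Gamma(a_n) - \log\Gamma(a) + a \log b - a_n \log b_{n,g}
  + \tfrac12 (\log c - \log c_n) - \tfrac n2 \log 2\pi .$$

Dimensions are independent under the model, so the cluster marginal is the
sum over dimensions (`clusterMarginalLogLik`). Fixing the prior mean location
$m$ at zero is deliberate: the package assumes (and warns when it does not
hold) that every column has been z-score normalized, so a cluster's
dimension-wise means scatter around zero. The closed form is exercised
against brute 2-D numerical quadrature of the defining integral in the test
suite; any disagreement beyond $10^{-6}$ relative error is treated as an
implementation error, not a tolerance matter.

## Greedy agglomeration and the merge probability

Starting from singletons, the algorithm repeatedly merges the pair of
clusters with the highest posterior probability of belonging to a single
component. For a candidate merge $D_k = D_i \cup D_j$ the DPM supplies a
prior through the recursion

$$d_k = \alpha\,\Gamma(n_k) + d_i d_j, \qquad \pi_k = \alpha\,\Gamma(n_k)/d_k,$$

with $d = \alpha$, $\pi = 1$ at leaves, and the subtree evidence follows

$$p(D_k \mid T_k) = \pi_k\, p(D_k \mid H_1) +
  (1 - \pi_k)\, p(D_i \mid T_i)\, p(D_j \mid T_j), \qquad
  r_k = \frac{\pi_k\, p(D_k \mid H_1)}{p(D_k \mid T_k)}.$$

$r_k$ is the posterior probability of the merged hypothesis. Once the full
binary tree is built, the flat partition is obtained by descending from the
root and splitting every node with $r \le 0.5$ (`cutTree`); the number of
clusters falls out automatically. The boundary case $r = 0.5$ splits: only
mergers that are strictly more likely than not survive.

The concentration $\alpha$ (default 1) tunes the expected number of
clusters — larger $\alpha$ favours more clusters — and is held fixed rather
than optimized; an invariant test asserts the cluster count is non-decreasing
in $\alpha$ on well-separated data.

## Hyperparameter inference

Two empirical-Bayes schemes set $(c, a, b)$; both work on
$(\log c, \log a, \log b)$ so positivity never needs explicit constraints.

**TREE** (`scheme = "tree"`, `optimizeTree`) seeks one shared triple for the
whole dataset by maximizing the root marginal likelihood
$p(D \mid T_{\text{root}})$. Gradients of that objective are tractable only
for a fixed hierarchy, so the implementation alternates: build the tree under
the current triple, then improve the triple with the structure frozen
(Nelder–Mead on the three log-parameters, with the frozen-structure root
marginal recomputed in compiled code), and rebuild. The loop keeps the best
(triple, tree) pair and stops when a rebuild no longer improves the root log
marginal likelihood, or after `maxRounds` (default 20) rounds, so the
recorded trace is non-decreasing by construction. A derivative-free inner
optimizer was chosen over propagating analytic gradients through the
recursion because the inner problem is only three-dimensional and each
objective evaluation is linear in the number of nodes; the monotone-ascent
contract is what the tests pin down.

**NODE** (`scheme = "node"`) gives every candidate merger its own triple by
maximizing the hyperparameter posterior

$$\log p(c, a, b \mid D_k) \propto \log p(D_k \mid c, a, b)
  + \textstyle\sum_{\theta \in \{c,a,b\}} \log \text{Gamma}(\theta; k_\theta, r_\theta),$$

by conjugate-gradient ascent (Polak–Ribière with backtracking) using the
analytic digamma gradients implemented in `nodeGradient` and verified against
central finite differences. Each merged node's $r$ uses its own optimized
triple for $p(D_k \mid H_1)$, while the children contribute the subtree
marginals they stored when they were created — hyperparameter inference is
local to each merger, which is what makes a single construction pass
sufficient. Candidate optimizations are warm-started from the larger child's
triple and cached; only pairs involving the newly created cluster are
re-optimized after a merge, keeping the total number of optimizations
quadratic in the number of observations.

The gamma hyper-priors default to shape 2, rate 2 on each of $c$, $a$, $b$
(mode $1/2$, mean 1): weakly informative on the unit scale that z-scored data
live on, and proper enough to regularize small clusters. They are
configurable through `hyperPrior()`; the concrete values are this package's
own committed choice.

### Numerical choices

* All probability arithmetic is in log space; $\Gamma(n_k)$ appears only as
  `lgamma` (it overflows past $n_k \approx 170$ otherwise).
* Near the root, $\alpha\,\Gamma(n_k)$ dominates $d_i d_j$ so strongly that
  $\log \pi_k$ computed by subtraction rounds to exactly 0. The engine
  therefore computes $r$ from the difference of the two hypotheses' log
  weights with $\log d_k$ cancelled algebraically — a form that stays exact
  however extreme the imbalance.
* Greedy ties break toward the lexicographically smallest pair of positions
  in the creation-ordered cluster list, making reruns byte-identical.
* Degenerate clusters (a dimension with all values identical, $s_g = 0$) need
  no special casing: $b_{n,g} \ge b > 0$ keeps the closed form finite.
* Conjugate-gradient stopping: gradient norm below $10^{-6}$, or two
  consecutive objective improvements below $10^{-8}$, capped at 200
  iterations (a lone tiny improvement can be a backtracked step far from the
  optimum, hence the two-in-a-row rule).
* Empty clusters are legal inputs to the posterior update and gradient: the
  likelihood terms vanish exactly and only the prior remains.

### A known small-sample degeneracy

With very few observations the TREE objective can be flat along a ridge
where $(c, a, b)$ grow without bound; in the extreme two-observation case the
precision becomes effectively known, the merged and split hypotheses assign
identical likelihood, and $r$ lands exactly on the 0.5 boundary (which the
cut rule splits). The NODE scheme's hyper-priors remove this ridge. This is a
property of unpenalized empirical Bayes at tiny $n$, not of the
implementation; it is harmless at realistic sample sizes, where the tests
show both schemes agreeing.

## What the synthetic generators emulate

The three generators (`simulateScenario1/2/3`) produce labelled benchmark
data in the regime the model targets and two regimes that break its
assumptions:

1. **Scenario 1** — $k = 7$ spherical Gaussians in $d = 10$ dimensions,
   equal weights, means on distinct coordinate axes at distance 8 in units of
   the component standard deviation. Every model assumption holds, so the
   generating partition should be recovered exactly.
2. **Scenario 2** — the same mixture with exchangeable within-component
   correlation $\rho$ (default 0.5). The independent-dimensions assumption
   fails; large correlated clusters look increasingly non-Gaussian to the
   model, which responds by refusing late merges — the characteristic failure
   mode is over-segmentation into sub-clusters, and the tests assert the
   inferred count exceeds the true 7.
3. **Scenario 3** — seven components from heterogeneous families (Gaussian,
   gamma(2,1), uniform, Student's t with 5 df, Weibull shape 1.5, chi-squared
   4 df, each standardized to zero mean and unit variance with independent
   dimensions, plus one correlated Gaussian). Marginal non-Gaussianity with
   independence largely preserved degrades accuracy only mildly.

Assignments are drawn first, then coordinates, from a single documented seed;
every generator ends with the package's own z-score normalization, so output
always satisfies the model's input contract. Component separations and
weights are this package's committed defaults and can all be overridden.

What the generators do **not** emulate: microarray noise models, batch
effects, heavy class imbalance, outlier contamination, or realistic
gene–gene correlation structure. Passing the benchmark tests therefore shows
the algorithm recovers structure under its stated assumptions and degrades in
the documented directions — it does not certify performance on any particular
real dataset.

## Preprocessing protocol

For expression data the intended pipeline is fixed: `log2Transform`, then
`wilcoxonFilter` (two-sided rank-sum test between two phenotype groups,
significance level 0.001; exact enumeration when both groups have at most 15
observations and no ties, tie-corrected normal approximation otherwise), then
`zscoreNormalize` (sample variance with the $n-1$ denominator — the choice is
immaterial after rescaling but fixed for reproducibility).
`preprocessExpression` enforces the order, so retained columns end up exactly
normalized. For gene clustering, probes are observations and samples are
variables; for sample clustering the transpose — `readExpressionMatrix`'s
`orientation` flag applies the convention at load time, and normalization
always acts on the columns of the oriented matrix.

## Evaluation indices

`adjustedRandIndex` is the Hubert–Arabie chance-corrected pair-counting
index, implemented directly from the contingency table; it is not clamped at
zero because small negative values are meaningful (worse than chance). `bhi`
is the biological homogeneity index: the mean, over clusters with at least
two annotated members, of the fraction of annotated within-cluster pairs
sharing at least one functional class; items with empty class sets are
excluded from pair counts, and annotations are entirely user-supplied (no
ontology retrieval).

## Problem sizes and budgets

The benchmark tests and the acceptance script use $n = 300$, $d = 10$,
$k = 7$ with five seeds per claim — sizes chosen so the full suite runs on a
single CPU in minutes while leaving the mixture geometry (separation,
dimensionality, component count) untouched. At these sizes a NODE fit costs
roughly ten seconds and a TREE fit well under one. Memory in the engine is
dominated by the candidate-score cache, quadratic in $n$; desk-scale inputs
(up to a few thousand observations) are the intended regime.

## Known limitations

* Correlated dimensions within a cluster are outside the model; expect
  over-segmentation that grows with the number and strength of correlated
  pairs. Decorrelating transforms help but change the meaning of the
  variables.
* Greedy agglomeration commits to each merge; there is no backtracking or
  stochastic tree search.
* The TREE objective can possess local optima (it is non-convex); the outer
  loop guarantees monotone improvement, not global optimality.
* $\alpha$ is fixed, not inferred. An inappropriate $\alpha$ biases the
  inferred number of clusters in the documented direction.
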