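# gbhc — Gaussian Bayesian hierarchical clustering for expression data

`gbhc` clusters the observations of an expression matrix (samples, or probes
for gene clustering) without being told the number of clusters and without an
*ad hoc* distance metric. It is aimed at transcriptomics practitioners who
want model-based hierarchical structure: each merge in the dendrogram is
ranked by the posterior probability that the two clusters came from a single
mixture component, and the final flat partition falls out of cutting the tree
where that probability drops to one half.

## The model

Data are assumed z-score normalized. Within a cluster, every dimension *g*
is an independent Gaussian with unknown mean and precision under a conjugate
normal-gamma prior (mean location fixed at 0):

    x_ig | mu_g, tau_g ~ N(mu_g, 1/tau_g),   (mu_g, tau_g) ~ NG(0, c, a, b)

so each cluster's marginal likelihood is closed-form: with c_n = c + n,
a_n = a + n/2 and b_n,g = b + ssd_g/2 + c n xbar_g^2 / (2(c+n)),

    log p(x_g) = lgamma(a_n) - lgamma(a) + a log b - a_n log b_n,g
                 + (log c - log c_n)/2 - (n/2) log 2*pi.

Merges are scored under a Dirichlet process mixture: the merge prior follows
the recursion d_k = alpha*Gamma(n_k) + d_i d_j, pi_k = alpha*Gamma(n_k)/d_k,
the subtree evidence is
p(D_k|T_k) = pi_k p(D_k|H1) + (1 - pi_k) p(D_i|T_i) p(D_j|T_j), and the
posterior merge probability is r_k = pi_k p(D_k|H1) / p(D_k|T_k). Two
empirical-Bayes schemes set the hyperparameters (c, a, b):

* **TREE** — one shared triple, found by alternating tree builds with
  fixed-structure maximization of the root marginal likelihood;
* **NODE** — a triple per merger, maximizing the hyperparameter posterior
  under gamma hyper-priors by conjugate-gradient ascent with analytic
  digamma gradients (about an order of magnitude faster on real matrices).

The package also ships the surrounding protocol: log2 transform, Wilcoxon
rank-sum feature filtering (significance 0.001), z-score normalization,
synthetic benchmark generators with ground-truth labels, the adjusted Rand
index and the biological homogeneity index, Newick dendrogram export, and a
command-line interface (`inst/scripts/gbhc`) with `simulate`, `cluster`,
`evaluate` and `filter` subcommands.

## Worked example

```r
library(gbhc)

sim <- simulateScenario1(n = 300, d = 10, k = 7, seed = 1)  # labelled benchmark
fit <- gbhc(sim$data, scheme = "node")
fit
#> GBHCFit: 300 observations, scheme = NODE, alpha = 1
#>   root log marginal likelihood: -2932.3031
#>   cut at r <= 0.5: 7 clusters
#>   hyperparameters: c = 2.975, a = 1.923, b = 1.679

adjustedRandIndex(partition(fit), sim$labels)
#> [1] 1
```

The fit recovered all 7 generating components exactly (adjusted Rand index 1;
an index of 0 would mean chance-level agreement). The first merges join
points of the same component with merge probability r = 1; the final,
cross-component merges are only forced because agglomeration must end in one
cluster, and their r is vanishingly small (the last three are about 4e-117,
9e-220 and 0), which is why cutting at r <= 0.5 leaves exactly the 7 real
clusters:

```r
head(mergeProbabilities(fit), 3)   # 1 1 1
tail(mergeProbabilities(fit), 3)   # 3.76e-117 8.90e-220 0
table(partition(fit), sim$labels)  # 7x7 table, one block per component
writeDendrogram(fit, "tree.nwk")   # Newick with r annotations
```

The same pipeline from the shell:

```sh
inst/scripts/gbhc simulate --scenario 1 --n 300 --d 10 --k 7 --seed 1 \
    --out-matrix m.tsv --out-labels lab.tsv
inst/scripts/gbhc cluster --input m.tsv --scheme node --out-partition part.tsv \
    --out-dendrogram tree.nwk
inst/scripts/gbhc evaluate --partition part.tsv --reference lab.tsv
```

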