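---
title: "Methods: empirical Bayes replicability analysis across study clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical Bayes replicability analysis across study clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Given an $n \times m$ matrix of p-values or z-scores — gene $i$ tested in
study $j$ — we want the genes whose association is *k-replicable*: truly
non-null in at least $k$ of the $m$ studies. Each study $j$ follows a
two-groups model: a gene is null with prior probability $\pi_0^j$, its
statistic drawn from $f_0^j$, and non-null otherwise, drawn from $f_1^j$.
The latent state of gene $i$ is a binary configuration vector
$h \in \{0,1\}^m$, and conditional on $h$ the statistics are independent
across studies:
$P(Z_{i,\cdot} \mid h) = \prod_j f_0^j(Z_{ij})^{1-h_j} f_1^j(Z_{ij})^{h_j}$.
The quantity reported per gene is the partial-conjunction local Bayes FDR

$$\mathrm{fdr}_k(Z_{i,\cdot}) \;=\;
  \sum_{h \,:\, |h| < k} P(h \mid Z_{i,\cdot}),$$

the posterior probability that the gene is non-null in fewer than $k$
studies. Genes with $\mathrm{fdr}_k \le 0.2$ (the conventional local-fdr
threshold) are declared k-replicable; a more permissive $0.4$ buys extra
coverage at the cost of a few false positives.

Three estimators of the configuration prior $\pi(h)$ are provided:

* **`screen_ind`** — the studies are independent, so $\pi(h)$ factorizes
  into the fitted $\pi_0^j$. The $\mathrm{fdr}_k$ is then exact and computed
  in $O(nmk)$ by a count dynamic program (the posterior non-null count is
  Poisson-binomial with per-study success probability equal to the local
  tdr).
* **`repfdr_ub`** — all studies in one cluster; the prior is estimated by a
  *restricted EM* that keeps at most $n_H$ configurations, and the output is
  a proven upper bound on $\mathrm{fdr}_k$.
* **`screen`** — the full pipeline: studies are partitioned into clusters
  that are approximately independent of each other, the EM models each
  cluster, and per-cluster posterior count distributions are convolved by
  dynamic programming.

# Per-study model fitting (normix)

The default estimator works on absolute z-scores (p-values are first mapped
through $z = \Phi^{-1}(1-p)$, clipped into $[10^{-15}, 1-10^{-15}]$ so $z$
stays finite; for one-sided input p-values both tails of the z-scale then
carry signal, which the absolute-value treatment handles symmetrically).
The mixture is

$$|z| \sim \pi_0 \cdot \mathrm{HN}(s) + (1 - \pi_0) \cdot |N(\mu, 1)|,
  \qquad s \ge 1,\; \mu > 0,$$

with the half-normal null and a *folded* normal non-null. The folded form
was chosen over a truncated normal because it is a proper density on
$[0,\infty)$ for every $\mu$ and admits an exact EM via a latent sign
indicator, so every M-step is closed form and the log-likelihood is
provably non-decreasing (the $s \ge 1$, $\mu > 0$ constraints are enforced
by projection, which still maximizes the constrained Q-function because Q
is unimodal in each parameter). The non-null standard deviation is fixed at
1; freeing it adds little at these sample sizes and destabilizes fits with
weak signal. Defaults: start at $\pi_0 = 0.9$, $s = 1$, $\mu$ at the 75th
percentile of $|z|$; tolerance $10^{-6}$ on the log-likelihood; at most
1000 iterations. With `null = "theoretical"` (the pipeline default) $s$ is
pinned at 1: on data with dense effects an estimated empirical null
swallows part of the signal and inflates $\pi_0$, and the fixed theoretical
null proved the more robust choice.

A simplified locfdr-style estimator for signed z-scores is also provided
(`fit_locfdr_style`): maximum-likelihood truncated-normal fit of an
empirical null on $|z| \le 2$, falling back to central matching and then to
the theoretical null whenever the estimated $\pi_0$ exceeds 1. It is a
spline-free re-implementation; numerical equality with the published locfdr
package is not a goal.

**Power shrinkage.** Each study's power is estimated as the expected tdr
under its non-null density, $\mathrm{E}_{f_1}[1 - \mathrm{fdr}(z)]$
(trapezoidal integration, 2001 grid points). $f_1$ is then multiplied by
the power and deliberately *not* renormalized: the model describes a
pointwise down-weighting of non-null evidence, not a density transform.
Low-power studies therefore contribute less to every downstream posterior,
which makes all reported fdr values stringent (biased upward).

# Restricted EM and the fdr upper bound

The unrestricted EM over a support $H'$ alternates posterior configuration
probabilities (E) and their average (M); zero probabilities are absorbing,
so constraining the support just means starting from it. When $2^m$ is too
large, the restricted EM builds the prior study by study under a memory cap
$n_H$: each round extends every retained configuration by 0 and 1, re-runs
the EM on the extended support, rescales by the retained mass $\xi$, keeps
the top $n_H/2$ configurations, and updates $\xi$ (now smaller) and
$\varepsilon$ (the largest probability ever discarded — valid because a
prefix bound caps every extension). Two points were genuinely open and
resolved as follows:

* *Warm start within a round*: the EM restarts from the previous round's
  probabilities split equally between the 0- and 1-extensions (floored at
  $10^{-12}$ so extensions of EM-zeroed configurations stay reachable).
  This is a concrete instance of the deterministic-start requirement.
* *Final round and the $n_H = 2^m$ edge*: truncation to $n_H/2$ exists only
  to make room for the next extension, so the last round keeps up to $n_H$
  configurations; and when $2^m \le n_H$ the full space fits and the
  unrestricted EM is used directly, making the restricted fit exactly equal
  to the unrestricted one with $\xi = 1$, $\varepsilon = 0$. Ties at the
  retention boundary are broken toward lexicographically smallest
  bit-vectors for determinism.

Given the retained prior and $\varepsilon$, the fdr upper bound is

$$\mathrm{fdr}_k \le
  \frac{\sum_{|h|<k,\,h\in H'} P(Z|h)\,(\pi(h)-\varepsilon)
        \;+\; \varepsilon \sum_{|h|<k} P(Z|h)}
       {\sum_{h\in H'} P(Z|h)\,\pi(h)},$$

capped at 1; the middle sum runs over *all* low-count configurations and is
computed by the same count dynamic program without priors, so the per-gene
cost is $O(m(n_H + k))$.

# Clustering the studies

For each pair of studies the EM is run over the four joint configurations;
the estimated $\pi(1,1)$ is the shared non-null probability $a_{ij}$, and
with the marginals $a_i = 1 - \pi_0^i$ taken from the per-study fits the
correlation is the phi coefficient
$r_{ij} = (a_{ij} - a_i a_j)/\sqrt{a_i(1-a_i)a_j(1-a_j)}$, clipped to
$[-1,1]$. Each $r_{ij}$ is the mean of 100 bootstrap runs
($\lfloor n/2 \rfloor$ genes sampled with replacement; replicates warm-start
from the full-data fit with a capped iteration count, so the bagged mean
hugs the full-data estimate, which is its target). The graph with edges at
$|r| \ge 0.1$ — carrying $|r|$ as edge weight — is clustered with the
map-equation (infomap) algorithm under a fixed seed; isolated studies
become singletons. The weights matter: the pairwise $a_{ij}$ estimator has
a standard error around 0.05–0.08 when the two-groups fit is weakly
identified (weak signal), so a fraction of truly independent pairs always
lands just above the 0.1 threshold. On an *unweighted* graph those
borderline edges let the random walk leak between genuinely distinct blocks
and infomap merges them; with $|r|$ weights the strong within-block edges
(0.6–0.95) dominate the flow and block recovery is exact. A
connected-components fallback is exposed (unweighted by nature, and more
sensitive to spurious edges).

One numerical pitfall surfaced during development and shaped the design:
the *pair EM must use the unshrunken $f_1$*. The marginals $a_i$ come from
the unshrunken fits, and running the pair EM on power-shrunken likelihoods
systematically depresses $a_{ij}$ below $a_i a_j$, turning truly
independent pairs into spurious negative correlations strong enough to pass
the $|r| \ge 0.1$ edge threshold. Shrinkage is therefore applied everywhere
*except* in the correlation stage, where the two estimators must be
consistent.

# Merging clusters

Within each cluster the EM yields a posterior distribution of the non-null
count per gene (counts absent from the retained configuration set get
probability zero, and the posterior is renormalized over the retained mass
— the optimistic policy; the interaction of the $\varepsilon$ correction
with the cross-cluster convolution is not specified by the merge formulas,
and renormalization keeps the merged value a proper probability). A cluster
of size $c$ can host $0..c$ non-nulls, so the count table has $c+1$ columns
— the base case of the merge recursion is bounded at $k^* \le |C_1| + 1$,
not $k^* < |C_1|$, otherwise the top counts are dropped and rows stop
summing to one. Counts of independent clusters add, distributions convolve,
and $\mathrm{fdr}_k$ is the merged mass on counts $0..k-1$ (the driver sums
the first $k$ table entries; summing only $k-1$ of them, as a literal
reading of the printed recursion suggests, contradicts the definition of
$\mathrm{fdr}_k$ and the $k = m+1 \Rightarrow \mathrm{fdr} = 1$ boundary
case, so the definition wins).

# Synthetic data

`simulate_independent` emulates sparse independent effects: 5000 genes, 20
studies, 300 non-nulls drawn without replacement per study, non-null
p-values from the 50/50 mixture $\tfrac12\beta(1,x) + \tfrac12\beta(x,1)$
(both tails of a one-sided test; $x \in \{10, 100, 1000\}$ gives mean low
p-values of 0.1, 0.01, 0.001), nulls Uniform(0,1). A block of 50 genes is
additionally planted with $\beta(1,x)$ draws in 5 extra studies drawn
*independently per gene*. The per-gene draw is a deliberate design choice:
planting all 50 genes in one shared set of 5 studies raises those studies'
pairwise phi to about 0.13, which exceeds the 0.1 edge threshold — the
clustering stage then (correctly!) groups them and the scenario stops being
an independent-studies benchmark. With per-gene study sets the pairwise
excess co-occurrence is negligible and the clustering returns singletons,
which is the behavior the scenario is meant to test.

`simulate_clustered` emulates dependent studies: 4 blocks of 10 studies,
rows of a latent Gaussian matrix drawn from a block-exchangeable
$N(0, \Sigma)$ (one-factor construction), a cell non-null when the latent
value exceeds the 0.94 standard-normal quantile (6% per study, i.e. 300 of
5000), p-values as above. `oracle_fdr_clustered` computes each gene's
*true* $\mathrm{fdr}_k$ under this generative model (quadrature over the
shared factor for the exchangeable prior, true Uniform/Beta densities,
exact count convolution) and serves as the independent ground truth for
calibration tests.

Neither generator reproduces gene–gene dependence within a study, realistic
p-value histograms of microarray data, or study-size heterogeneity; green
tests on them establish algorithmic correctness and calibration under the
stated model, not robustness to real-data violations.

# Numerical choices and limitations

* Likelihood products over configurations are computed in log space and
  row-shifted before exponentiation inside the EMs (row scaling cancels in
  the E-step); the independence DP works on posterior ratios in $[0,1]$ and
  needs no scaling. The raw-likelihood products inside the upper bound are
  safe in double precision up to roughly $m \approx 100$ studies.
* EM convergence: absolute log-likelihood change below $10^{-6}$
  ($10^{-5}$ inside bootstrap replicates, where only the mean of 100
  estimates is consumed); at most 2000 iterations, warning on
  non-convergence.
* The pipeline is deterministic given the master seed: per-pair bootstrap
  seeds derive from it, the community search is seeded, and the EMs have
  deterministic starts.
* $\mathrm{fdr}_k$ values from `screen` on clusters that required
  truncation are heuristic (EM local optima, optimistic renormalization);
  `repfdr_ub` gives the certified upper bound instead. No variance is
  attached to any fdr estimate.
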