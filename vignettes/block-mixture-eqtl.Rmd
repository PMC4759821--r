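---
title: "Mapping eQTLs for gene clustering with a Gaussian block mixture"
author: "blockeqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping eQTLs for gene clustering with a Gaussian block mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

An eQTL mapping experiment on a two-genotype cross (backcross, or
recombinant-inbred homozygotes treated the same way) yields an
$n \times m$ expression matrix $x_{ij}$ (individuals $\times$ transcripts),
marker genotypes coded $\{0, 1\}$, and a genetic map. `blockeqtl` places
two independent latent label sets on this matrix:

* a column label $w_j \in \{1, \dots, L\}$ assigning transcript $j$ to one
  of $L$ expression clusters, drawn i.i.d. with probabilities $\pi_l$;
* a row label $z_i \in \{1, 2\}$, the unobserved genotype of individual
  $i$ at a candidate eQTL, with prior $p_{ik}$ given by classical interval
  mapping from the flanking-marker genotypes and the candidate position.

Given the labels, cells are independent Gaussians,
$x_{ij} \mid z_i = k, w_j = l \sim N(\mu_{kl}, \sigma^2_{kl})$. Summing
over all joint label configurations is intractable, so estimation
maximises the per-cell *composite likelihood*

$$\ell_c(\Theta) = \sum_{i=1}^n \sum_{j=1}^m \log \sum_{k=1}^{K}
  \sum_{l=1}^{L} p_{ik}\, \pi_l\, \phi(x_{ij}; \mu_{kl}, \sigma_{kl}),$$

in which every cell contributes its marginal mixture density. Rows and
columns of the matrix are exchangeable but not independent; the composite
likelihood deliberately ignores that dependence. Two consequences shape
the package's design: (i) information-matrix standard errors would be
wrong, so all inference runs through permutation; (ii) a BIC-type penalty
is heuristic, and we state exactly which one we use (below).

### Two-layer EM

`fit_em()` maximises $\ell_c$ by an EM algorithm on the per-cell surrogate.
The E step computes joint cell responsibilities
$t_{ijkl} \propto p_{ik} \pi_l \phi(x_{ij}; \mu_{kl}, \sigma_{kl})$
(log-space with a per-cell log-sum-exp; the pass over cells is compiled
code). The M step updates
$\pi_l = \tfrac{1}{nm}\sum_{ijk} t_{ijkl}$, block means as
responsibility-weighted cell means, and block SDs as weighted SDs (or one
pooled SD with `variance = "pooled"`). The genotype prior $p_{ik}$ is
*fixed* throughout — it carries the genetic map information and is never
re-estimated. Every iteration increases $\ell_c$; the trace is checked in
the tests.

Numerical choices:

* **Initialisation.** Column clusters by k-means on transcript profiles
  (the first start uses five k-means restarts); block means from the
  prior-weighted cluster means. Additional `n_starts` run k-means afresh
  from random centers, which explores genuinely different column
  partitions — perturbing one solution proved unable to escape merged-
  cluster optima. The best start by final $\ell_c$ wins.
* **Convergence.** $|\Delta \ell_c| < 10^{-6}(1 + |\ell_c|)$, at most 500
  iterations.
* **Degeneracy.** Block SDs are floored at $10^{-4}$ of the global SD; a
  cluster whose responsibility mass vanishes aborts the start (collapse)
  rather than continuing silently.
* **Label order.** After fitting, clusters are re-ordered so
  $\mu_{1l}$ is ascending; reports are reproducible without an arbitrary
  label convention. MAP ties break toward the lowest index.
* **RNG hygiene.** Every seeded function snapshots and restores the
  caller's RNG stream. This matters: the permutation loops draw a fresh
  permutation per iteration, and an internal `set.seed()` that leaked
  into the caller's stream would silently freeze them.

### Genetics

Map distances convert to recombination fractions by the Haldane map
function $r = (1 - e^{-2d/100})/2$ (no interference), consistent with
multiplying flip probabilities across sub-intervals. At a candidate
position with flanking genotypes $(a, b)$ and sub-interval fractions
$(r_1, r_2)$, the genotype prior is the renormalised product of the two
transmission factors — e.g. $P(\text{same as both flanks}) =
(1-r_1)(1-r_2) / [(1-r_1)(1-r_2) + r_1 r_2]$ for concordant flanks. A
missing flanking genotype falls back to the single informative flanking
marker; two missing flanks give the uniform prior. Only $K = 2$ designs
are supported; no map expansion for advanced intercross generations is
applied (RIAIL data are treated as two homozygote classes), a documented
limitation.

## Choosing the number of clusters

`cl_bic()` scores a converged fit by
$-2 \ell_c + d \log(nm)$ with
$d = (L - 1) + KL + \{KL \text{ or } 1\}$ free parameters (proportions,
means, block or pooled SDs). The penalty sample size is the number of
composite-likelihood terms $nm$; users comparing a $\log m$ convention
can do so from the reported $\ell_c$ values directly.

`select_L()` fits every candidate $L$ with multi-start EM and returns the
CL-BIC minimiser, keeping the whole curve. One design point deserves
emphasis: **selection needs an informative genotype prior.** Under a
uniform prior ($p_{ik} = 1/K$) the $K \times L$ block means are
exchangeable free components — nothing ties row-layer components to
specific rows — so a $K = 2$ fit with too few clusters can park its
"genotype" means on extra clusters and reach essentially the same
composite likelihood as the true $L$; CL-BIC then underselects. We
observed exactly this on simulated data. The packaged workflow therefore
screens markers by aggregate expression association (`screen_markers()`,
a sum of squared two-group mean differences) and selects $L$ with the
interval-mapping prior at the winning marker (`best_marker_prior()`).
With the genotype layer anchored, the CL-BIC curve shows a clean elbow at
the generating $L$ in simulation.

## The genome scan and hypothesis tests

`scan_genome()` slides the candidate eQTL along a 1 cM grid (plus every
marker), refits the full model at each position, and compares it once
against a position-independent genotype-collapsed null ($K = 1$, same
$L$) through $\mathrm{CLR} = 2(\ell_c^{full} - \ell_c^{null})$. The argmax
estimates the eQTL position. Fits warm-start along the grid; any position
whose CLR would come out negative is refit from the null-expanded model,
which starts EM exactly at the collapsed optimum and so guarantees
$\mathrm{CLR} \ge 0$ — an optimisation guard, not a change of statistic.

`permutation_threshold()` permutes individual rows of the genotype data
against the fixed expression rows — preserving marker LD and expression
covariance while destroying genotype–expression linkage — re-scans per
permutation, and takes the empirical $(1-\alpha)$ order statistic of the
genome-wide maxima. Permuted scans reuse the observed per-position fits
as warm starts; we verified on null simulations that cold chained
restarts give the same permutation distribution, so the reuse costs
nothing statistically. Empirical size at $\alpha = 0.05$ sits inside the
binomial band in the test suite's 100-replicate null study.

Four composite-LR tests interrogate a fitted position:

1. **Any cluster** (`test_any_cluster()`): $\mu_{1l} = \mu_{2l}$ for all
   $l$; identical to the scan statistic at that position.
2. **Given cluster** (`test_per_cluster()`): the equality imposed on one
   cluster only, all others free; a constrained refit. Across clusters,
   Benjamini–Hochberg adjustment is reported.
3. **Genotype × cluster interaction** (`test_interaction()`): the
   genotype effect is a common shift, $\mu_{1l} - \mu_{2l} = c$. The
   constrained M step solves the weighted least-squares system for
   $(a_l, c)$ given the current SDs, then updates SDs (conditional
   maximisation, still monotone). On top of the CLR, each cluster pair is
   classified *magnitude*-varying (same effect sign, different size) or
   *direction*-varying (opposite signs).
4. **Cluster structure** (`test_cluster_structure()`): within-genotype
   cluster contrasts are genotype-independent,
   $\mu_{1l} - \mu_{1l'} = \mu_{2l} - \mu_{2l'}$ for all pairs. For
   $K = 2$ this constraint space coincides with the additive null of
   test 3 — the two tests differ in what they report (centered
   genotype-profile contrasts versus pairwise interaction classes), a
   genuinely open corner of the formulation that we resolved by making
   the shared constraint explicit rather than inventing a distinction.

Position-level p-values for tests 2–4 permute the prior rows and refit
both models per permutation, starting permuted full fits from the
constraint-projected model so observed and permuted statistics are
comparable.

## Cluster networks

`cluster_scores()` averages expression over each MAP cluster (or
posterior-weighted, on request); `build_network()` computes Pearson
correlations of those scores across individuals and retains edges with
$|r| \ge 0.3$ by default — the figures this supports encode correlation
sign and magnitude, and no principled threshold exists, so the default is
deliberately conservative and adjustable. `genotype_conditional_networks()`
repeats this within each MAP genotype class at an eQTL and lists edges
retained in exactly one class.

## What the simulator emulates — and what it does not

`sim_design()` / `backcross_design()` generate: markers on a 50 cM group
(six evenly spaced by default), Markov genotypes along the map with
Haldane flip probabilities, one eQTL at 24 cM, i.i.d. categorical cluster
labels, and Gaussian cells. The reference design uses $n = 208$
individuals and, at full scale, $m = 5450$ transcripts in $L = 43$
clusters; `scale` shrinks $m$ (and proportionally $L$) for desk-scale
studies. The generating block parameters are not published for the system
this emulates, so the package fixes a calibrated regime once: unit
within-block SD, uniform $\pi$, cluster base means 3 SD apart, and
genotype effects $0.8\sigma$ times an alternating-sign magnitude cycle
$\{1, 0.6, 1.4\}$ — separation strong enough that cluster recovery is
reliable, effects varied enough that magnitude- and direction-varying
interactions both occur.

Real expression data differ in ways the generator does not emulate:
within-cluster correlation beyond the block mean, heavy tails and
outliers, cluster-size imbalance, multiple and linked eQTLs, and
genotyping error. Passing tests on this generator demonstrate internal
correctness and statistical calibration of the method under its own
model, not robustness to those violations.

Validation problem sizes (chosen to keep a full run on one CPU
comfortable): position recovery uses 50 replicates of the scale-0.1
design ($m = 545$, $L = 4$, 1 cM grid); selection uses 50 replicates at
$n = 208$, $m = 300$, $L_{true} = 5$, grid $3..8$, four EM starts per
candidate; the null calibration uses 100 small replicates with 100
permutations each.

## Known limitations

* $K = 2$ designs only; no F2/outbred support, no interference-aware map
  functions, no genotype imputation beyond the flanking fallback.
* One eQTL at a time; linked eQTLs will blur into single peaks.
* The composite likelihood treats cells independently: model-based
  standard errors are unavailable by construction, and CL-BIC's penalty
  is a convention (stated above), not a theorem.
* Cluster labels are exchangeable across fits; compare runs through the
  canonical ordering, not raw label identity.
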