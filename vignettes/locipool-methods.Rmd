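---
title: "Weighted pooling of multi-locus distances: models, choices and limits"
author: "locipool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted pooling of multi-locus distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the distance and variance estimators, the four pooling schemes and what each
optimizes, the simulation model behind the efficiency experiments, and the
numerical conventions adopted where the mathematics alone does not decide.

## 1. The estimation model

A multi-locus dataset is a set of per-gene alignments over one shared taxon
set. Within each gene, every site is assumed to evolve at the same rate;
*across* genes, rates differ. All distances are computed per gene, after
per-gene complete deletion (every column holding a gap or ambiguity code in
any retained taxon is removed), so each gene contributes its own usable
length $L_h$.

For amino-acid loci the number of substitutions per site between taxa $i$
and $j$ is estimated by the Poisson correction of the proportion $p$ of
differing sites,
$$k = -\ln(1-p), \qquad V[k] = \frac{p}{L(1-p)},$$
the variance following from the binomial variance of $p$ by the delta
method. For DNA loci the Kimura two-parameter correction separates the
transition proportion $P$ (A$\leftrightarrow$G, C$\leftrightarrow$T) from
the transversion proportion $Q$:
$$k = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q),$$
with the classical delta-method variance
$V = (c_1^2 P + c_3^2 Q - (c_1 P + c_3 Q)^2)/L$, where $c_1 = 1/(1-2P-Q)$,
$c_2 = 1/(1-2Q)$, $c_3 = (c_1+c_2)/2$. Both variances are evaluated at the
*estimated* proportions — deliberately so, since the behaviour of the
weighting methods under estimation noise is exactly what the package is
built to study. Rate variation among sites *within* a gene is not modelled;
that is a known limitation of both estimators as used here.

Tests verify the two delta-method variances against direct Monte-Carlo
resampling (binomial and multinomial, $10^5$ draws at $L = 1000$), with
agreement well within 10%.

## 2. The four pooling schemes

Let $k_h(i,j)$ and $V_h(i,j)$ be the per-gene estimates, $\mu_h$ and $v_h$
their means over unordered taxon pairs, and $w$ nonnegative weights
normalized to sum to one within each pair. The pooled distance is
$D(i,j) = \sum_h w_h(i,j)\,k_h(i,j)$ — always a convex combination, so
$D(i,j)$ lies between the smallest and largest per-gene distance for that
pair.

* **No-weight** — $w_h \propto L_h$. Equivalent to concatenating the genes
  site by site; the baseline.
* **Least squares (`ls`)** — $w_h(i,j) \propto 1/V_h(i,j)$, one weight per
  gene *and pair*: the minimum-variance linear combination when all genes
  share one expected distance. Because $\hat V$ is strongly correlated with
  $\hat k$, a gene that happens to underestimate a distance also
  underestimates its variance and is up-weighted for that pair only, which
  distorts the relative geometry of the matrix. The simulations reproduce
  the expected consequence: `ls` is consistently the worst method.
* **Modified Tajima–Takezaki (`mtt`)** — a single weight per gene,
  $w_h \propto \mu_h / v_h$, which maximizes the accuracy index
  $$A(w) = \frac{\sum_h w_h \mu_h}{\sqrt{\sum_h w_h^2 v_h}},$$
  the expected pooled distance over the standard deviation of its sampling
  error ($A$ is scale-invariant in $w$; the maximizer follows from the
  stationarity condition $\mu_h \propto w_h v_h$). Tests confirm the closed
  form beats a $10^4$-point random search over the weight simplex.
* **Modified least squares (`mls`)** — a single weight per gene,
  $w_h \propto 1/v_h$, the minimizer of the pooled variance
  $\sum_h w_h^2 v_h$ on the simplex.

Gene-level aggregation for `mtt` and `mls` uses *unweighted* means of $k$
and $V$ over pairs: under rate constancy the pairs are exchangeable, and a
single per-gene weight is the point of both modifications. (Aggregating by
$1/\bar v$ rather than $\overline{1/v}$ is likewise deliberate: the mean of
reciprocals is infinite as soon as one pair is identical, whereas a nearly
invariant gene should receive a large but finite weight.)

### Zero-variance boundary

A gene with no observed differences for a pair has $\hat V = 0$ exactly,
and inverse-variance weights would hand it *all* the weight, zeroing out
every informative gene — under `mls`, a single fully invariant gene would
then make the pooled matrix identically zero and leave the topology to
tie-breaking. We instead charge a zero variance estimate the variance of the
smallest divergence the gene can resolve, $p^* = 1/(2L)$, i.e.
$V^* = p^*/(L(1-p^*))$ — the same convention the distance estimators use at
the saturation boundary (below). With $L = 500$ this weight is still some
500 times a typical gene's, so the methods' documented sensitivity to
near-zero divergence is fully preserved (an `mls`-weighted analysis is still
dominated by nearly invariant genes, which is why `runBootstrapStudy()`
supports `exclude` for repeating an analysis without them); but informative
genes retain nonzero weight, and because an invariant gene adds the same
zero to every pair, neighbor joining's scale invariance leaves the topology
driven by the informative genes. There is no default variance floor beyond
this boundary convention.

### Saturation

When divergence is so large that a logarithm argument is nonpositive
($p \ge 1$, or $1-2P-Q \le 0$, or $1-2Q \le 0$), the distance is undefined.
Interactive use errors; inside simulation and bootstrap replicates
(`clamp = TRUE`) the offending argument is replaced by $1/(2L)$ — the
smallest resolvable non-identity — and the replicate is flagged and counted
(`saturated_replicates`). Discarding such replicates would bias the
proportion-correct statistic at high rates, where failures are informative;
they are therefore retained in denominators by default.

## 3. Tree reconstruction and comparison

Neighbor joining is implemented directly (Saitou–Nei agglomeration,
Studier–Keppler $Q$-criterion, standard branch-length formulas) so that its
tie-break is fully specified: among pairs minimizing $Q$, the pair whose
sorted cluster labels are lexicographically smallest is joined, a cluster
being labelled by its smallest member leaf. This makes reconstruction — and
therefore every PC value and bootstrap count — deterministic and invariant
to taxon input order, which an index-based tie-break cannot guarantee.
Negative branch lengths are retained (they never affect topology) and
counted in an attribute. Tests cross-check topologies against `ape::nj` and
require exact recovery on random additive matrices.

Topologies are compared unrooted (NJ is unrooted) by the partition metric:
the number of non-trivial bipartitions in exactly one tree, delegated to
`phangorn::RF.dist` and validated against brute-force split enumeration in
the tests. A replicate counts toward PC iff this distance is zero, so PC and
mean topological distance are two views of the same comparison.

Bootstrap support resamples columns with replacement *within* each locus
(weights are gene-level quantities, so resampling must respect gene
boundaries), recomputes distances, variances, weights, the pooled matrix and
the NJ tree in every replicate, and counts replicates containing the queried
clade. One master seed spawns a child seed per replicate, and within a
replicate each locus' resampling stream is keyed by the locus *name*, so
counts are reproducible replicate-by-replicate and invariant to locus order.

## 4. The simulation model

The generator emulates clock-like multi-locus evolution:

* **Model trees.** Two built-in ultrametric 8-taxon trees with all internal
  branches 0.1 T: tree A, the fully asymmetric caterpillar (tip depths
  0.1–0.7 T, longest path 1.4 T), and tree B, the fully balanced tree
  (every branch 0.1 T, longest path 0.6 T). The two printed path-length
  constraints (1.4 T and 0.6 T) and the 0.1 T branch unit fix these shapes;
  any Newick tree can be substituted.
* **Rates.** One rate per locus, $u(h) \sim \Gamma$ with shape $a$ and mean
  $u$, so $E[u(h)] = u$ and $V[u(h)] = u^2/a$; $a = \infty$ disables rate
  variation. Drawn with `stats::rgamma`.
* **Substitution.** Exact Poisson event counts per site per branch (expected
  $t \cdot u(h)$ substitutions per site on a branch of length $t$), not
  matrix exponentials, mirroring the generative description. Amino acids:
  20-state equal-rates model (each event moves to one of the other 19
  states uniformly). DNA: Kimura two-parameter process with
  transition : single-transversion-type rate ratio $\kappa$ (default 4, a
  typical mammalian value; the ratio is configurable since no canonical
  value is implied by the design).
* **Defaults.** 10 loci of 500 sites each — the scale of organellar
  protein-coding genes. Non-clock mode multiplies every branch of every
  locus by an independent lognormal factor with mean 1 (log-sd
  $\sigma = 0.5$ by default).

Calibration tests pin the process to closed forms: the 20-state model's
expected $p$-distance $(19/20)(1 - e^{-(20/19)\,2tu})$ within 1% at
$L = 10^5$; $P/Q \to 1/2$ at $\kappa = 1$; uniform amino-acid stationarity
(chi-square); gamma moments within 3 standard errors over $10^4$ loci.

What the generator does **not** emulate — and what passing simulations
therefore cannot certify about real data: realistic amino-acid exchange
matrices, within-gene site-rate variation, context effects such as CpG
hypermutability, indels and alignment error, and gene-tree/species-tree
discordance (all loci share one tree by construction).

## 5. The efficiency experiments

`runPCExperiment()` measures, per weighting method, the proportion PC of
simulation trials whose reconstructed unrooted topology equals the
generating one, alongside the mean partition distance. All methods see the
same simulated data within a trial (paired design), so method contrasts are
not diluted by simulation noise; with a single locus all four methods
coincide, which the tests use as a consistency check. Wilson score intervals
at 99% summarize binomial uncertainty. `runGrid()` sweeps either $a$ (rate
heterogeneity) or $u$ (overall divergence), the two axes along which the
methods separate.

The package's own acceptance runs use 500 trials per grid point and confirm
the expected ordering at $u = 0.5$, $a = 0.3$: both modified methods at
least match the no-weight baseline on both model trees, per-pair least
squares falls clearly behind, PC declines with growing $u$, and the
asymmetric tree is harder than the symmetric one. These are trend checks —
500-trial proportions carry ~±0.05 of binomial noise and are not intended
as precise point estimates.

The among-locus gamma shape can be recovered from data via the moment
estimator $\hat a = m^2/v$ applied to the per-gene distance estimates of one
taxon pair (`estimateGammaShape()`, with the per-pair table from
`pairGammaTable()`); the estimator inverts $V[u(h)] = u^2/a$ and is
consistent but noisy for few genes, so it is reported as a descriptive
summary, not an inferential quantity.

## 6. Degenerate inputs and edge policies

* Complete deletion may leave zero columns; distance computation then
  refuses the locus (a length-0 gene estimates nothing).
* Identical datasets (all distances zero) are legal everywhere: `mtt` falls
  back to length weights with a warning (no signal to weight by), NJ
  resolves by its deterministic tie-break, and bootstrap counts remain
  reproducible.
* Taxon matching is by exact label; a taxon missing from any locus is an
  error naming both.
* Ambiguity codes (N, X, ?, and friends) are treated as gaps: only columns
  where every taxon carries an unambiguous residue enter distances, which
  is the point of complete deletion.

## 7. Known limitations

Only the two distance families above are provided (no gamma-corrected or
model-based distances); weighting quality is bounded by the quality of
$\hat V$, which these simple estimators tie tightly to $\hat k$ — the very
effect that makes `ls` underperform. The bootstrap driver assumes all loci
cover the same taxa (no missing-data patterns). The simulator's independence
of loci given the tree means it cannot probe linked-locus effects. Finally,
the application workflow expects externally aligned genes; alignment
uncertainty is outside the model.
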