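---
title: "Training-set optimization for genomic selection in hybrid populations"
author: "hybridTS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-set optimization for genomic selection in hybrid populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridTS)
```

## The problem

Hybrid breeding programs screen large candidate populations of crosses
between inbred parents to find the few hybrids with the highest true
breeding values (TBVs). Phenotyping every candidate is infeasible, so a
*training set* of $n_t$ hybrids is phenotyped, a genomic prediction model
is fitted, and all candidates are ranked by their genomic estimated
breeding values (GEBVs). The quality of that ranking depends strongly on
*which* $n_t$ candidates are phenotyped. `hybridTS` implements
training-set construction criteria that account for both additive and
dominance genetic effects — the latter being the genetic basis of
heterosis and therefore essential in hybrids — together with the
prediction model, ranking metrics, and a simulation framework to compare
construction methods end to end.

## Model

Marker calls for a candidate population of $n_c$ hybrids at $p$ biallelic
SNPs are coded per locus as additive scores $w^A \in \{1, 0, -1\}$ for
{AA, AB, BB} and dominance scores $w^D \in \{0, 1, 0\}$ (heterozygote
indicator). Each column is standardized to sample mean 0 and sample
standard deviation 1 ($n_c - 1$ denominator), giving score matrices
$X_A$ ($n_c \times p_A$) and $X_D$ ($n_c \times p_D$). The genomic
relationship matrices are

$$K_A = X_A X_A^\top / p_A, \qquad K_D = X_D X_D^\top / p_D.$$

Standardization makes $\mathrm{tr}(K_A) = \mathrm{tr}(K_D) = n_c - 1$ and
all row sums zero, which the test suite asserts as invariants. The
phenotype model is the additive + dominance GBLUP model

$$y = 1\mu + g_A + g_D + e, \qquad
g_A \sim N(0, \sigma^2_A K_A), \quad
g_D \sim N(0, \sigma^2_D K_D), \quad
e \sim N(0, \sigma^2_e I).$$

### Why per-matrix marker counts

The kinship denominators use each matrix's own retained column count.
Dominance columns are constant whenever no sampled cross segregates at a
locus, and such columns are dropped before standardization; dividing each
Gram matrix by its own retained count keeps the trace identity exact for
both kernels. Dropped columns are reported in the `score_pair`
bookkeeping rather than silently discarded.

## Construction criteria

Three criteria score a candidate subset $t$ of size $n_t$; all work from
genotypes only — selection never sees phenotypes.

**Ridge MSPE.** With candidate score rows $X_c$ and training rows $X_t$
(principal-component scores, below), and
$A = X_t^\top (X_t X_t^\top + \lambda I)^{-1}$,

$$\mathrm{MSPE}^{(v2)} = \mathrm{tr}[X_c A A^\top X_c^\top]
 + \mathrm{tr}[(X_c - X_c A X_t)(X_c - X_c A X_t)^\top],$$

the (variance + squared bias) of a ridge predictor of every candidate's
scores from the training rows; lower is better. It is an affine transform
of the mean squared prediction error itself
($\mathrm{MSPE} = 1 + \mathrm{MSPE}^{(v2)}/n_c$), so both forms have the
same minimizer; the tests assert this equivalence on random instances.
$\lambda$ defaults to 1; ridge regularization makes the $n_t \times n_t$
system nonsingular for any $\lambda > 0$, and the implementation solves
the system rather than forming the inverse.

**Heuristic mean CD.** With
$G = \alpha_A K_A + \alpha_D K_D$ (variance ratios
$\alpha_\bullet = \sigma^2_\bullet/\sigma^2_e$), training block $G_t$,
candidate-by-training block $G_{ct}$, and centering matrix
$M_t = I - \bar J_{n_t}$,

$$\mathrm{CD}^{(v2)} = \sum_{i=1}^{n_c} \frac{A_i}{B_i}, \qquad
A_i = \big[G_{ct}(M_t G_t + I)^{-1} M_t G_{ct}^\top\big]_{ii}, \quad
B_i = \big[G\big]_{ii},$$

the sum over candidates of the squared correlation between true and
BLUP-predicted genotypic values; higher is better. The error variance
cancels between numerator and denominator, so only the ratios matter, and
they default to $\alpha_A = \alpha_D = 1$; `robustness_report()`
quantifies how insensitive the subset ranking is to that choice. A
candidate with numerically zero genomic variance ($B_i \le 10^{-12}$) has
no rankable signal; its term contributes 0 with a warning rather than a
division by zero.

**Genomic-variance ranking (A-optimality-like).** Candidate $i$ scores
$\sigma^2_A K_A[i,i] + \sigma^2_D K_D[i,i]$, its own genomic variance.
Because the trace of a subset's kernel submatrix is the sum of its
members' scores, the subset criterion is modular and the exact optimum is
the top-$n_t$ ranking — no search needed. Positive rescaling of
$(\sigma^2_A, \sigma^2_D)$ with a fixed ratio never changes the ranking,
which is the basis of the scale-invariance check in the acceptance suite.
Defaults are $\sigma^2_A = \sigma^2_D = 1$.

### Principal-component reduction

The MSPE criterion operates on the merged matrix $[X_A, X_D]$, which can
have tens of thousands of columns. It is replaced once, for the whole
candidate population, by scores on the leading principal directions — the
smallest number of components whose cumulative explained variance exceeds
0.99. Training-set rows used during subset search are row subsets of this
single score matrix: a shared basis keeps criterion values comparable
across subsets, and at threshold 1 the Gram matrix (hence the criterion)
is reproduced exactly.

## The exchange optimizer

MSPE and CD are non-modular, so subsets are optimized by steepest-ascent
exchange: from a seeded uniform random subset, each round evaluates all
$n_t \times (n_c - n_t)$ single swaps and applies the best strictly
improving one, stopping when none improves or after `max_rounds` (default
50). Design choices, made for determinism and testability:

* *Steepest ascent, not first-improvement*: given a start, the trajectory
  is unique, so runs are exactly reproducible.
* *Strict improvement* (tolerance $10^{-12}$): guarantees termination and
  a monotone criterion trajectory, which tests assert.
* *Tie-breaks by ascending candidate index* everywhere (also in rankings
  and metrics): continuous criteria make ties measure-zero, but the rule
  removes any platform dependence of sort order.
* *Default `n_restarts = 1`* mirrors a single optimization run; local
  optima exist, and on small instances the unit tests compare against
  exhaustive enumeration — the exchange never exceeds the global optimum
  and reaches it from most starts, but the hit rate is instance-dependent,
  so criterion value rather than set identity is the meaningful output.

On a modular objective (the genomic-variance sum) the exchange provably
reaches the exact top-$n_t$ set from any start, which the tests use as an
oracle.

## Closed-form BLUP

GEBV prediction uses the closed-form BLUP under the generative model:

$$\hat g_t = (M_t + G_t^{-1})^{-1} M_t y_t, \qquad
\hat g_c = G_{ct} (M_t G_t + I)^{-1} M_t y_t.$$

The centering matrix absorbs the fixed mean, so predictions are invariant
to location shifts of the phenotypes. These formulas are algebraically
identical to Henderson's mixed-model equations after eliminating the
intercept, and to the conditional-expectation BLUP with a GLS-estimated
mean; the test suite verifies both equivalences on 50 random instances at
$10^{-8}$ relative tolerance.

The variance ratios $\alpha_A, \alpha_D$ are taken as known — in the
simulation study they are the true generative ratios. This deliberately
isolates training-set quality from variance-component estimation noise
and keeps every replicate deterministic given its seed; a user fitting
real data supplies externally estimated ratios through the same
arguments. A Bayesian or REML fit of the variance components is outside
the package's scope. When the training kernel is ill-conditioned
(condition number $> 10^{12}$, possible for near-identical hybrids in
$K_D$), a jitter of $10^{-8} \times$ mean diagonal is added, with a
message.

## Ranking metrics

Let $\pi_1, \ldots, \pi_k$ be the TBV ranks (1 = best) of the top-$k$
candidates by GEBV. The package reports, at depth $k$ (default 20):

* **NDCG@k** — discounted cumulative gain of the predicted ordering over
  that of the ideal ordering, gain $f(v) = v$ on the TBVs and discount
  $1/\log_2(i+1)$; 1 iff the predicted top-$k$ ordering is ideal. Gains
  are raw TBVs ($\mu + g$); with $\mu = 100$ they are positive in
  practice, and the large mean compresses NDCG differences between
  methods. Negative gains void the $[0,1]$ range and raise a warning, not
  an error.
* **SRC@k** — the Pearson correlation of the pairs $(i, \pi_i)$, i.e.
  the rank correlation within the selected set.
* **RS_ratio@k** — $\sum_{i \le k} i \,/\, \sum_{i \le k} \pi_i$; equals
  1 iff the selected set *is* the true top-$k$ (in any order).

Methods are summarized by the relative improvement percentage over random
sampling, $\mathrm{RIP} = 100 (\bar M_i - \bar M_0)/\bar M_0$.

The three metrics answer different questions: RS_ratio and NDCG measure
*identification* of the best $k$; SRC measures *ordering within* the
selected $k$, conditioned on whatever set was selected. That conditioning
matters when interpreting simulation trends (below).

## The synthetic data generator

`simulate_hybrid_genotypes()` emulates an elite hybrid panel: `n_male`
(default 15) and `n_female` (default 120) fully homozygous inbred
parents; per locus a minor-allele frequency $f \sim U(0.1, 0.5)$ (the
lower bound mirrors the usual MAF > 0.1 filter); each parent carries the
minor allele, homozygously, with probability $f$; `n_hybrids` (default
500) crosses are sampled uniformly without replacement and a hybrid is
AA/AB/BB according to whether 0/1/2 of its parents carry the minor
allele. Loci monomorphic across the sampled hybrids are redrawn up to 10
times, then dropped. The default 2,000 markers are far fewer than a real
SNP array but enough for stable kinships at $n_c = 500$; the marker count
only enters through $K_A, K_D$.

What the generator does **not** emulate: linkage disequilibrium and
recombination maps (loci are independent), population structure beyond
the male × female factorial, genotyping error, and missingness. Passing
tests therefore demonstrate correctness of the methods under the stated
generative model, not robustness to those real-data features.

`sim_scenario()` fixes the phenotype model at $\mu = 100$,
$\sigma^2_A = 20$, $\sigma^2_D = \gamma\,\sigma^2_A$ with
$\gamma \in \{0.5, 1, 2, 4\}$ (a range bracketing empirical
dominance-to-additive ratios reported for cereal yield traits), and
$\sigma^2_e = \frac{1-h^2}{h^2}(\sigma^2_A + \sigma^2_D)$ with broad-sense
$h^2 \in \{0.3, 0.6\}$. Genetic effects are drawn by symmetric
eigendecomposition of the kinships with negative eigenvalues clipped at
zero (the kernels are rank-deficient by construction, so a Cholesky
factor need not exist); an eigenvalue below $-10^{-6}$ aborts, since it
indicates a corrupted matrix rather than roundoff. Because the score
columns are centered, $\mathbf 1^\top K \mathbf 1 = 0$ and
$\mathrm{tr}(K) = n_c - 1$, so the expected sample variance of each
genetic component equals its variance component exactly — the basis of
the simulator-recovery checks.

Reproducibility: a root seed spawns one substream seed per replicate
index, so replicate $r$ is bit-identical whether generated alone or in a
batch, and the same replicates are reused across construction methods
within a scenario (common random numbers), which makes the random
method's RIP over itself exactly 0 and sharpens method contrasts.

## The simulation study and its scale

`run_study()` wires the pipeline: select one set per (method, size) from
genotypes only; per scenario $(\gamma, h^2)$ simulate shared replicates;
per replicate compute all-candidate GEBVs from the training subset's
phenotypes and the three metrics at $k$; summarize means, SDs and RIPs.

Default problem sizes are chosen for a desktop: 200 replicates per
scenario (the full-scale design uses 2,000; `n_reps = 2000` or the CLI's
`--full-scale` reproduces it), candidate populations of 500, and the
test suite exercises the exchange-based methods at small $n_c$ only —
full-neighborhood exchange over 500 candidates costs hours per set for
the CD and MSPE criteria (the genomic-variance ranking is instantaneous
at any scale, which is its main practical appeal). The acceptance checks
run the full $\gamma \times h^2 \times n_t$ grid at 200 replicates with
the random and genomic-variance methods in about a minute.

### What the trends show

On the synthetic population, NDCG@20 and RS_ratio@20 reproduce the
expected qualitative behavior within one Monte-Carlo standard error:
both improve with $n_t$, degrade as $\gamma$ grows, and improve with
$h^2$, for every method tested. SRC@20 reproduces only the $h^2$ trend.
Its $\gamma$ trend actually *reverses*: as identification degrades, the
true ranks of the selected set spread over a wider range, and a wider
spread mechanically inflates a correlation computed on those pairs, even
though the selected set is truly worse. This is a property of
conditioning the metric on the selected set, not a defect of the
implementation (SRC passes exact hand-computed oracles and all
invariants); reports based on SRC@k alone should be interpreted with
that caveat.

## Numerical choices

* All inverses are linear solves; $(M_t G_t + I)$ is treated as a general
  system since $M_t G_t$ is not symmetric.
* Zero-variance score columns are dropped per matrix; each kinship
  divides by its own retained count.
* PC threshold comparisons use a $10^{-12}$ fudge so a threshold of
  exactly 1 retains precisely the numerical rank.
* Criterion evaluations are pure functions of (matrices, index set); the
  optimizer re-evaluates rather than caching, which keeps memory flat and
  is not the bottleneck at the scales where exchange is practical.
* Degenerate inputs fail loudly: unknown genotype symbols name the cell,
  missing genotypes are rejected (no imputation — inputs are assumed
  pre-filtered upstream), an all-monomorphic marker set is an error, and
  multi-allelic VCF records are dropped with a count.

## Known limitations

* Variance components are inputs, not estimates; there is no
  REML/Bayesian machinery.
* The exchange schedule is a deterministic steepest-ascent stand-in for
  exchange-type optimizers in general; different schedules reach
  different local optima, so criterion values, not selected-set identity,
  are the comparable quantity across implementations.
* No linkage, epistasis, genotype-by-environment interaction, or
  multi-cycle gain; the simulator draws independent loci and a single
  trait in a single environment.
* NDCG with the default linear gain on TBVs is compressed by the large
  general mean; differences between methods show mainly in SRC and
  RS_ratio.
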