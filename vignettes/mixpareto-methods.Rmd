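---
title: "MixPareto: models, simulator and design choices"
author: "MixPareto authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MixPareto: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genome-wide breeding value (GWEBV) estimation predicts the additive genetic
merit of selection candidates from dense SNP genotypes, using a training set
of individuals with both genotypes and phenotypes.  Methods differ mainly in
the prior placed on marker effects.  SNP-BLUP / GBLUP gives every marker the
same normal prior — fast, but blind to the possibility that a few loci carry
large effects.  Bayesian mixture models (BayesB and relatives) allow a small
fraction of large effects, but are fitted by MCMC and are orders of
magnitude slower.

MixPareto implements **MixP**: a two-component normal mixture prior whose
component variances are *fixed in advance by the Pareto principle*, fitted
by a deterministic per-marker posterior-mean iteration.  The mixture gives
BayesB-like accuracy; fixing the variances removes a hyper-parameter and
makes an MCMC-free solver possible.

## The MixP model

Records are modelled as

$$ y = \mu 1 + \sum_i b_i g_i + e, \qquad e \sim N(0, I\sigma_e^2), $$

where $b_i$ is the *standardized* genotype column of marker $i$: dosage $d$
at allele frequency $p_i$ maps to $(d - 2p_i)/\sqrt{2p_i(1-p_i)}$, so a
column in Hardy–Weinberg proportions has mean 0 and variance 1.  The prior
on each marker effect is

$$ p(g_i) = \pi\,\phi(g_i \mid 0, \sigma_1^2)
          + (1-\pi)\,\phi(g_i \mid 0, \sigma_2^2). $$

The Pareto principle — $x\%$ of the markers explain $(100-x)\%$ of the
genetic variance, generalized to $0 < x \le 50$ — fixes both variances from
$\pi = x/100$, the total genetic variance $V_g$ and the marker count $M$:

$$ \sigma_1^2 = \frac{(1-\pi)V_g}{\pi M}, \qquad
   \sigma_2^2 = \frac{\pi V_g}{(1-\pi)M}, $$

which conserves $M(\pi\sigma_1^2 + (1-\pi)\sigma_2^2) = V_g$.  At
$\pi = 0.5$ both variances are $V_g/M$ and MixP *is* GBLUP — a property the
test suite checks numerically against a dense mixed-model-equation solve.
With $V_g$ treated as known (in practice, a REML estimate), the prior has a
single free hyper-parameter, $\pi$, which `cvGridSearch()` tunes by
cross-validation when no external estimate (such as a known QTL count) is
available.

### The iterative conditional expectation (ICE) solver

Each sweep visits every marker in fixed ascending column order.  For marker
$i$, the records corrected for everything else,
$\tilde y_i = y - 1\mu - \sum_{j \ne i} b_j \hat g_j$, admit a closed-form
posterior mean under the mixture prior: BLUP estimates $\hat g_{1i},
\hat g_{2i}$ under each component variance, combined with weights equal to
the posterior component probabilities obtained from the marginal
likelihoods $L_{1i}, L_{2i}$ of the single-marker model.  Those marginal
likelihoods involve the $n \times n$ covariance
$V = b_i b_i'\sigma^2 + I\sigma_e^2$, but the matrix determinant lemma and
the Sherman–Morrison identity reduce both $|V|$ and
$\tilde y' V^{-1} \tilde y$ to scalar expressions in $b'b$, $b'\tilde y$
and $\tilde y'\tilde y$ (`scalarLogLik()`), so no matrix is ever formed or
inverted.  `snpUpdate()` is the resulting per-marker operation; the test
suite verifies it against adaptive numerical quadrature of the posterior
integral, and `scalarLogLik()` against the explicit dense multivariate
normal density.

Numerical choices that matter:

* **Posterior odds in log space.** $L_{1i}$ and $L_{2i}$ underflow at
  realistic $n$; the weight is computed as
  $P_{1i} = 1/(1 + \exp(z))$ with
  $z = \log\frac{1-\pi}{\pi} + \log L_{2i} - \log L_{1i}$ clamped to
  $\pm 700$.
* **Mean scheduling.** $\mu$ is re-estimated once per sweep, before the
  marker updates, as the mean of the current residual added to the running
  value.  The scheduling is not dictated by the model; doing it once per
  sweep keeps the update order reproducible.
* **Residual bookkeeping.** The residual $r = y - 1\mu - B\hat g$ is
  maintained incrementally ($r \leftarrow r - b_i\Delta\hat g_i$) and
  recomputed from scratch every 25 sweeps and at convergence, bounding
  floating-point drift; a test compares the maintained residual with its
  from-scratch recomputation.
* **Convergence.** Iteration stops when
  $\sum_i (\Delta\hat g_i)^2 < 10^{-5} \sum_i \hat g_i^2$ (tunable `tol`).
  The relative criterion is undefined at an all-zero solution, so a
  non-zero change with zero solution norm never counts as converged; an
  *exactly* zero change (e.g. a constant phenotype) is an exact fixed point
  and does count.  The ceiling is 1000 sweeps — generous, as the solver
  typically needs fewer than 50 (the acceptance script measures a median
  of about 8–10 under the standard simulated scenario) — and reaching the
  ceiling is reported as a warning with `converged = FALSE`, not an error.
* **Degenerate columns.** A marker whose standardized column is constant
  after imputation ($b'b = 0$) is skipped with $\hat g_i = 0$.
* **$\pi$ domain.** $\pi$ is accepted only in $(0, 0.5]$; above 0.5 the
  "big" component would be the smaller-variance one and the Pareto reading
  would invert.

The sweep itself is implemented in C++ (as the fast genomic-prediction
packages do); the exported R operations `snpUpdate()` and `scalarLogLik()`
define the per-marker semantics, and a test pins one C++ sweep to the R
update loop exactly.

## Baselines

**GBLUP.**  The direct solver forms the intercept-augmented mixed-model
equations and solves them densely — exact, and used as the oracle in
several tests.  The iterative solver is per-marker Gauss–Seidel with the
same convergence rule as MixP; both solvers agree to $10^{-4}$ in
max-norm.  The direct solver is the default up to 5000
markers.

**BayesB-style sampler.**  The same two-component mixture, fitted by Gibbs
sampling with *sampled* variances: each big-component marker has a
locus-specific variance with a scaled inverse-$\chi^2(\nu = 4.2, S_1)$
prior, the small component shares one variance with prior
inverse-$\chi^2(\nu, S_2)$, the small effects acting as a polygenic
background.  Chain length 10000 with 3000 burn-in by default.  The
published description leaves the full conditionals and the scale
parameters open; we fixed a conjugate scheme — component indicator from
the effect-integrated likelihood ratio (reusing the scalar identities),
effect from its Gaussian full conditional, variances from their conjugate
scaled inverse-$\chi^2$ conditionals, mean from its Gaussian full
conditional — and anchored the scales so the prior *means* equal the
Pareto variances: $S_k = \sigma_k^2(\nu-2)/\nu$.  $\pi$ is fixed, not
sampled.  The residual variance is treated as known, matching how the
simulation study supplies variance components to all three methods.  A
seed is mandatory and stored.  Tests check the null-data posterior,
agreement of two chains, and convergence to GBLUP when $\pi \to 1$ with
the big variance pinned at $V_g/M$.

## The synthetic-data generator

The simulator emulates the study design of a dairy-cattle genomic
selection program evaluated on a real pedigree:

1. **Historical population** (`simulateIdealPopulation()`): neutral
   Wright–Fisher forward simulation of $2N_e$ haplotypes to mutation–drift
   balance; one chromosome of 1 Morgan / $10^8$ bp; Haldane crossovers
   (Poisson with mean equal to the map length, no interference);
   infinite-sites mutation on the integer bp grid.  Full-scale conditions
   are $N_e = 200$, 10000 generations, $\mu = 10^{-8}$ per bp.  The
   package's *desk-scale default* is $N_e = 100$ for 800 generations with
   $\mu$ doubled, preserving $\theta = 4N_e\mu L_{bp} = 800$ — the
   polymorphism level and LD scale that drive prediction accuracy — at a
   fraction of the computation.  A mutation drawn onto an
   already-segregating position is redrawn within its gamete; the residual
   collision probability across gametes is of order $10^{-4}$ per run and
   is ignored.  Fixed and lost sites are pruned each generation.  A test
   compares the equilibrium segregating-site count with Watterson's
   prediction $\theta \sum_{k=1}^{2N_e-1} 1/k$.
2. **Locus sampling** (`sampleLoci()`): markers and QTL are drawn uniformly
   from sites with minor-allele frequency $\ge 0.05$, QTL first, marker and
   QTL sets disjoint (whether the original design allowed a locus to be
   both is unstated; disjoint is the cleaner reading).
3. **Pedigree** (`generatePedigree()`): the real 19523-individual,
   8-generation cattle pedigree is not distributable, so its shape is
   emulated: layered generations, parents drawn uniformly from the
   previous layer, the last 2165 individuals flagged genotyped, the oldest
   1915 of them as training and the youngest 250 as evaluation.  Pedigrees
   are topologically sorted by construction and on file input.
4. **Gene drop** (`geneDrop()`): founders (and unknown-parent slots) draw
   haplotypes from the final historical generation — without replacement
   until the pool of $2N_e$ haplotypes is exhausted, then with replacement,
   which the default pedigree (about 4900 founder slots versus 200
   haplotypes) always reaches; every non-founder receives one recombinant
   gamete per parent; no new mutation.  Only the sampled loci are tracked.
   Mendelian consistency is tested exhaustively on small pedigrees and
   founder allele frequencies against pool frequencies.
5. **Trait** (`makeTrait()`): QTL effects are Laplace(0, 1); true breeding
   values are dosage-weighted sums; the *realized* genetic variance among
   training individuals (not the theoretical Laplace variance) anchors the
   residual variance $\sigma_e^2 = V_g(1-h^2_{chr})/h^2_{chr}$, because
   the analysis is supplied with the simulated variances themselves.  One
   phenotype per training individual, evaluation individuals genotype-only.
   $h^2_{chr}$ is a per-chromosome heritability: the design simulates one
   chromosome and scales heritability down proportionally, justified by the
   accuracy formula $r^2 = Nh^2/(Nh^2 + 4N_eLv)$ (`expectedAccuracy()`),
   which is invariant to scaling $h^2$ and $L$ down together.

One history and one pedigree are shared across the replicates of a
scenario (`runScenario()`), with loci, transmissions and QTL effects
re-drawn per replicate — mirroring a study design in which the pedigree is
a fixed real object and the historical population is simulated once per
scenario.  MixP receives $\pi = N_{QTL}/N_{mkr}$, the simulated $V_g$ and
$\sigma_e^2$; accuracy is the Pearson correlation between predicted and
true breeding values of the evaluation individuals.

**What the generator does not emulate:** selection, migration, non-random
mating, multiple chromosomes, genotyping error, missing-data patterns, and
the unbalanced family structure of a real cattle pedigree.  Passing tests
therefore demonstrate correctness of the methods under an idealized
neutral, single-chromosome architecture, not performance on real data.

## Cross-validation

`cvGridSearch()` runs (by default) ten replicates of ten-fold
cross-validation over a $\pi$ grid of 0.01–0.50 in steps of 0.01.  Within
each training fold, $V_g = h^2\,\mathrm{var}(y)$ and $\sigma_e^2 =
(1-h^2)\,\mathrm{var}(y)$ from the observed fold phenotypes (the variance
bookkeeping of the original analysis is not specified; the training-fold
phenotypic variance is the natural choice).  The held-out criterion is the
correlation between GWEBV and phenotype, averaged per fold and then across
folds and replicates (pooling across folds would be the other reading of
an ambiguous description; per-fold averaging weights folds equally).  The
full grid and the argmax are both reported because the response curve is
characteristically flat above $\pi \approx 0.2$ — a property the
acceptance suite checks on synthetic data.

## Problem sizes used by the tests

Unit tests run on constructed instances of tens to hundreds of
individuals.  The replicated-scenario checks use 20 replicates per
scenario (100 in the original design; directional claims are already
resolvable at 20), desk-scale history defaults, and the full emulated
pedigree; the BayesB comparison runs at 200 markers, within the marker
grid of the study, where 20 chains of 10000 iterations remain quick.  The
cross-validation flatness check uses a 300-individual training set, a
$\pi$ grid restricted to $[0.2, 0.5]$ in steps of 0.05 and two replicates.

## Known limitations

* $V_g$ and $\sigma_e^2$ are inputs, never estimated; pair the package
  with an external REML/GBLUP variance estimation step on real data.
* No polygenic co-fit alongside the marker effects; the small-effect
  mixture component plays that role implicitly.
* No standard errors for the marker effects (a parametric bootstrap is the
  natural extension).
* Single-chromosome simulation; multi-chromosome genomes are handled by
  scaling heritability, or by looping the generator externally.
* The VCF reader handles biallelic SNP GT fields only; dosage orientation
  counts the ALT (or '1') allele, and flipping an allele's orientation
  flips the signs of $b_i$ and $\hat g_i$ without changing predictions.
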