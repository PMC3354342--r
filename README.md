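# MixPareto

Genome-wide breeding value (GWEBV) estimation with a two-component normal
mixture prior on SNP effects whose variances are fixed by the **Pareto
principle** — the MixP method — together with GBLUP and BayesB-style
baselines, a forward-in-time population simulator with pedigree
gene-dropping, replicated accuracy evaluation, and cross-validated tuning
of the mixture proportion.

The package is aimed at quantitative geneticists and genomic-selection
researchers who want a fast, MCMC-free Bayesian-mixture alternative to
GBLUP, and a fully reproducible synthetic benchmark to evaluate it on.

## The method in brief

Records follow the standardized SNP regression model

    y = mu 1 + sum_i b_i g_i + e,        e ~ N(0, I sigma_e^2),

with dosage d at allele frequency p standardized to
(d − 2p)/sqrt(2p(1−p)).  Each marker effect has the mixture prior

    p(g_i) = pi N(0, sigma1^2) + (1 − pi) N(0, sigma2^2).

The Pareto principle — pi of the markers explain (1 − pi) of the genetic
variance V_g, with 0 < pi ≤ 0.5 — fixes both component variances:

    sigma1^2 = (1 − pi) V_g / (pi M),    sigma2^2 = pi V_g / ((1 − pi) M),

so that M (pi sigma1^2 + (1 − pi) sigma2^2) = V_g.  Given V_g, the prior
has a single hyper-parameter pi; at pi = 0.5 MixP reduces exactly to
GBLUP.  Fitting is by iterative conditional expectation: each marker
effect is replaced in turn by its posterior mean given the current
estimates of all others — a weighted average of the two per-component
BLUP estimates, with weights from the marginal likelihood ratio computed
by scalar (Sherman–Morrison) identities, never an n × n inverse.
Iteration stops when the summed squared changes fall below 1e-5 times the
summed squared solutions; typical runs converge in well under 50 sweeps.

## Worked example

Simulate the emulated cattle study (19523-individual layered pedigree,
1915 training / 250 evaluation bulls, 1500 markers, 30 QTL, per-chromosome
heritability 0.03) and compare MixP with GBLUP:

```r
library(MixPareto)

cfg  <- simConfig(nMarkers = 1500, nQtl = 30, h2Chr = 0.03)
pool <- simulateIdealPopulation(cfg, seed = 1)   # historical population
ped  <- generatePedigree(seed = 2)               # layered pedigree
sim  <- simulateDataset(cfg, seed = 3, pool = pool, pedigree = ped)

gTrain <- sim$genotypes[sim$trainingIds, ]
gEval  <- sim$genotypes[sim$evaluationIds, ]

prior <- paretoPrior(pi = sim$piNominal,               # N_QTL / N_mkr = 0.02
                     geneticVariance = sim$trait$realizedVg,
                     nMarkers = ncol(dosages(gTrain)))
fit <- fitMixP(gTrain, sim$phenotypes, prior, residVar = sim$trait$residVar)
fit
#> MixPFit: 1500 markers, pi = 0.02
#>    converged in 8 sweeps (tol 1e-05 )
#>   mu = -4.98266 , mean P(big) = 0.01784

accuracy(predict(fit, gEval), sim$trait$trueBv[sim$evaluationIds])
#> [1] 0.566

gb <- fitGblup(gTrain, sim$phenotypes, sim$trait$realizedVg, sim$trait$residVar)
accuracy(predict(gb, gEval), sim$trait$trueBv[sim$evaluationIds])
#> [1] 0.530
```

The accuracy is the correlation between predicted and true breeding values
of the evaluation (genotype-only) individuals; with few QTL the mixture
prior concentrates signal on the causal markers and beats the
equal-variance GBLUP prior.  `fitBayesB()` provides the MCMC mixture
baseline, `runScenario()` replicates whole scenarios, and
`cvGridSearch()` tunes pi by 10×10-fold cross-validation when the QTL
count is unknown.

A command-line front-end covering `simulate`, `fit`, `predict`,
`evaluate` and `cv` is installed at
`system.file("scripts", "mixp", package = "MixPareto")`; every run writes
a `manifest.json` sufficient to regenerate its outputs.

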