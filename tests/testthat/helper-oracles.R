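# Independent oracles and small in-code fixtures shared across test files.

# Dense multivariate-normal log density of ytilde under V = bb's2 + I ve,
# built explicitly -- the brute-force counterpart of the scalar identities.
denseLogLik <- function(yTilde, b, sigmaSq, residVar) {
  n <- length(yTilde)
  V <- tcrossprod(b) * sigmaSq + diag(residVar, n)
  -0.5 * (n * log(2 * pi) + as.numeric(determinant(V)$modulus) +
            drop(t(yTilde) %*% solve(V, yTilde)))
}

# Posterior mean of a single marker effect under the two-normal mixture
# prior by adaptive quadrature over g, log-scaled to avoid underflow.
quadPosteriorMean <- function(yTilde, b, pi, s1, s2, ve) {
  logf <- function(g) {
    vapply(g, function(gg) {
      -0.5 * sum((yTilde - b * gg)^2) / ve +
        log(pi * dnorm(gg, 0, sqrt(s1)) + (1 - pi) * dnorm(gg, 0, sqrt(s2)))
    }, 0)
  }
  # centre the scaling near the ridge solution to keep exp() in range
  g0 <- sum(b * yTilde) / (sum(b * b) + ve / max(s1, s2))
  width <- 10 * sqrt(max(s1, s2)) + abs(g0)
  scale <- max(logf(seq(g0 - width, g0 + width, length.out = 101)))
  den <- integrate(function(g) exp(logf(g) - scale), -Inf, Inf,
                   rel.tol = 1e-12)$value
  num <- integrate(function(g) g * exp(logf(g) - scale), -Inf, Inf,
                   rel.tol = 1e-12)$value
  num / den
}

# Random polymorphic dosage matrix with named rows/columns.
toyDosages <- function(n, M, seed, pmin = 0.15, pmax = 0.85) {
  withr::local_seed(seed)
  p <- runif(M, pmin, pmax)
  d <- vapply(p, function(pp) rbinom(n, 2, pp), integer(n))
  dimnames(d) <- list(paste0("id", seq_len(n)), paste0("m", seq_len(M)))
  d
}

# Simulated training data with a handful of causal markers; returns the
# pieces needed to fit and score.
toyTrainingData <- function(n = 100, M = 50, nCausal = 3, h2 = 0.5,
                            seed = 1) {
  withr::local_seed(seed)
  g <- MixPareto::GenotypeMatrix(toyDosages(n, M, seed + 1))
  B <- MixPareto::standardized(g)
  causal <- sort(sample(ncol(B), nCausal))
  eff <- rnorm(nCausal, 0, 1)
  tbv <- drop(B[, causal, drop = FALSE] %*% eff)
  vg <- var(tbv)
  ve <- vg * (1 - h2) / h2
  y <- setNames(tbv + rnorm(n, 0, sqrt(ve)),
                MixPareto::individualIds(g))
  list(genotypes = g, phenotypes = y, causal = causal, effects = eff,
       tbv = tbv, vg = vg, ve = ve)
}

# Hand-built haplotype pool: explicit haplotypes over explicit positions.
handPool <- function(haplotypes, positions, config = simConfig()) {
  counts <- vapply(positions, function(p)
    sum(vapply(haplotypes, function(h) p %in% h, TRUE)), 0L)
  structure(list(haplotypes = lapply(haplotypes, as.integer),
                 positions = as.integer(positions),
                 freq = counts / length(haplotypes),
                 config = config),
            class = "HaplotypePool")
}

# Small layered pedigree fixture used by the gene-dropping tests.
smallPedigree <- function() {
  Pedigree(id = c("f1", "f2", "f3", "f4", "o1", "o2", "o3", "g1", "g2"),
           sire = c(NA, NA, NA, NA, "f1", "f1", "f3", "o1", "o3"),
           dam = c(NA, NA, NA, NA, "f2", "f2", "f4", "o2", "o2"),
           genotyped = c(rep(TRUE, 9)),
           role = c(rep("training", 7), "evaluation", "evaluation"))
}

# Desk-scale-but-small simulation configuration for fast end-to-end tests.
smallSimConfig <- function(...) {
  defaults <- list(effectiveSize = 30L, nGenerationsHistory = 240L,
                   genomeLengthBp = 1e6, genomeLengthMorgan = 1,
                   mutationRate = 5e-7, nQtl = 5L, nMarkers = 50L,
                   h2Chr = 0.3)
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}
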