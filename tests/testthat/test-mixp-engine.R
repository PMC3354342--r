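test_that("the Pareto prior conserves the genetic variance", {
  p <- paretoPrior(0.5, 1, 100)
  expect_equal(p@sigma1Sq, 0.01)
  expect_equal(p@sigma2Sq, 0.01)
  p <- paretoPrior(0.2, 1, 1000)
  expect_equal(p@sigma1Sq, 0.8 / 200)
  expect_equal(p@sigma2Sq, 0.2 / 800)
  for (pi in c(0.01, 0.1, 0.37, 0.5)) {
    for (vg in c(0.3, 1, 42)) {
      for (M in c(1L, 17L, 5000L)) {
        pr <- paretoPrior(pi, vg, M)
        expect_equal(M * (pi * pr@sigma1Sq + (1 - pi) * pr@sigma2Sq), vg)
      }
    }
  }
  expect_error(paretoPrior(0, 1, 10), "0, 0.5")
  expect_error(paretoPrior(0.6, 1, 10), "0, 0.5")
  expect_error(paretoPrior(0.2, -1, 10), "positive")
})

test_that("scalar likelihood identities match the dense-matrix oracle", {
  withr::local_seed(2024)
  for (k in 1:20) {
    n <- sample(3:50, 1)
    b <- rnorm(n)
    yt <- rnorm(n, sd = 2)
    s2 <- runif(1, 0.001, 2)
    ve <- runif(1, 0.2, 3)
    sc <- scalarLogLik(yt, b, s2, ve)
    expect_equal(sc$loglik, denseLogLik(yt, b, s2, ve), tolerance = 1e-10)
    expect_equal(sc$gBlup, sum(b * yt) / (sum(b^2) + ve / s2))
  }
})

test_that("scalar likelihood degenerates correctly", {
  yt <- c(1, -2, 0.5)
  # b = 0: no marker information, plain iid Gaussian
  sc <- scalarLogLik(yt, rep(0, 3), 0.7, 1.3)
  expect_equal(sc$gBlup, 0)
  expect_equal(sc$loglik, sum(dnorm(yt, 0, sqrt(1.3), log = TRUE)))
  # sigma^2 = 0 equals the sigma^2 -> 0 limit
  b <- c(0.5, -1, 2)
  exact0 <- scalarLogLik(yt, b, 0, 1.3)
  limit <- scalarLogLik(yt, b, 1e-14, 1.3)
  expect_equal(exact0$loglik, limit$loglik, tolerance = 1e-8)
  expect_equal(exact0$gBlup, 0)
  expect_lt(abs(limit$gBlup), 1e-10)
})

test_that("the single-SNP update equals adaptive quadrature", {
  for (seed in 1:10) {
    withr::local_seed(seed)
    n <- sample(5:50, 1)
    p <- runif(1, 0.2, 0.8)
    b <- drop(standardizeDosages(matrix(rbinom(n, 2, p)), p))
    pi <- runif(1, 0.02, 0.5)
    vg <- runif(1, 0.5, 2)
    prior <- paretoPrior(pi, vg, sample(20:2000, 1))
    ve <- runif(1, 0.5, 2)
    yt <- rnorm(n, sd = 1)
    upd <- snpUpdate(yt, b, prior, ve)
    oracle <- quadPosteriorMean(yt, b, pi, prior@sigma1Sq, prior@sigma2Sq,
                                ve)
    expect_equal(upd$gHat, oracle, tolerance = 1e-6)
    expect_gte(upd$posteriorBig, 0)
    expect_lte(upd$posteriorBig, 1)
    expect_equal(upd$gHat, upd$posteriorBig * upd$gHatBig +
                   (1 - upd$posteriorBig) * upd$gHatSmall)
  }
})

test_that("identical component variances give posterior weight pi", {
  prior <- paretoPrior(0.5, 1, 100)  # sigma1 = sigma2
  yt <- c(0.3, -1, 2, 0.1)
  b <- c(1, -1, 0.5, 2)
  upd <- snpUpdate(yt, b, prior, 1)
  expect_equal(upd$posteriorBig, 0.5)
  expect_equal(upd$gHatBig, upd$gHatSmall)
  expect_equal(upd$gHat, upd$gHatBig)
  # zero corrected records: everything collapses to zero
  upd0 <- snpUpdate(rep(0, 4), b, paretoPrior(0.1, 1, 100), 1)
  expect_equal(upd0$gHatBig, 0)
  expect_equal(upd0$gHatSmall, 0)
  expect_equal(upd0$gHat, 0)
})

test_that("one C++ sweep reproduces the R per-SNP update loop", {
  dat <- toyTrainingData(n = 60, M = 25, seed = 11)
  B <- standardized(dat$genotypes)
  y <- unname(dat$phenotypes)
  prior <- paretoPrior(0.1, dat$vg, ncol(B))
  cppState <- suppressWarnings(
    MixPareto:::mixp_fit_cpp(B, y, prior@pi, prior@sigma1Sq,
                             prior@sigma2Sq, dat$ve, 0, 1L, 25L))
  # reference sweep in R using the exported per-SNP operation
  mu <- mean(y)
  r <- y - mu
  mu <- mu + mean(r); r <- r - mean(r)
  g <- numeric(ncol(B))
  for (i in seq_len(ncol(B))) {
    yt <- r + B[, i] * g[i]
    upd <- snpUpdate(yt, B[, i], prior, dat$ve)
    r <- r - B[, i] * (upd$gHat - g[i])
    g[i] <- upd$gHat
  }
  expect_equal(cppState$g_hat, g, tolerance = 1e-12)
  expect_equal(cppState$mu, mu, tolerance = 1e-12)
})

test_that("with pi = 0.5 MixP converges to the dense GBLUP solution", {
  dat <- toyTrainingData(n = 100, M = 200, nCausal = 20, seed = 21)
  prior <- paretoPrior(0.5, dat$vg, 200)
  fit <- fitMixP(dat$genotypes, dat$phenotypes, prior, dat$ve, tol = 1e-7)
  gb <- fitGblup(dat$genotypes, dat$phenotypes, dat$vg, dat$ve,
                 solver = "direct")
  expect_lt(max(abs(markerEffects(fit) - markerEffects(gb))), 1e-4)
  expect_lt(abs(fit@mu - gb@mu), 1e-4)
})

test_that("a constant phenotype converges immediately to mu with zero effects", {
  g <- GenotypeMatrix(toyDosages(30, 10, seed = 31))
  y <- setNames(rep(3.25, 30), individualIds(g))
  fit <- fitMixP(g, y, paretoPrior(0.2, 1, 10), 1)
  expect_true(fit@converged)
  expect_equal(fit@iterations, 1L)
  expect_equal(fit@mu, 3.25)
  expect_equal(unname(markerEffects(fit)), rep(0, 10))
})

test_that("the converged solution is a fixed point", {
  dat <- toyTrainingData(n = 80, M = 40, seed = 41)
  prior <- paretoPrior(0.1, dat$vg, 40)
  tol <- 1e-7
  fit <- fitMixP(dat$genotypes, dat$phenotypes, prior, dat$ve, tol = tol)
  expect_true(fit@converged)
  # one extra sweep from the converged state barely moves the solution
  B <- standardized(dat$genotypes)
  y <- unname(dat$phenotypes)
  g0 <- unname(markerEffects(fit))
  r <- fit@residual
  mu <- fit@mu + mean(r); r <- r - mean(r)
  g <- g0
  for (i in seq_along(g)) {
    upd <- snpUpdate(r + B[, i] * g[i], B[, i], prior, dat$ve)
    r <- r - B[, i] * (upd$gHat - g[i])
    g[i] <- upd$gHat
  }
  # the extra sweep's squared change stays within 10x the convergence band
  expect_lt(sum((g - g0)^2) / sum(g0^2), 10 * tol)
})

test_that("row permutation leaves the converged solution unchanged", {
  dat <- toyTrainingData(n = 70, M = 30, seed = 51)
  prior <- paretoPrior(0.15, dat$vg, 30)
  fit1 <- fitMixP(dat$genotypes, dat$phenotypes, prior, dat$ve, tol = 1e-9)
  perm <- withr::with_seed(1, sample(individualIds(dat$genotypes)))
  fit2 <- fitMixP(dat$genotypes[perm, ], dat$phenotypes[perm], prior,
                  dat$ve, tol = 1e-9)
  expect_equal(markerEffects(fit1), markerEffects(fit2), tolerance = 1e-10)
})

test_that("BLUP components shrink monotonically with the variance ratio", {
  withr::local_seed(61)
  n <- 40
  b <- rnorm(n)
  yt <- rnorm(n) + b * 0.8
  lastBig <- Inf
  for (s2 in c(2, 1, 0.5, 0.1, 0.01)) {  # decreasing s2 = increasing ve/s2
    g <- scalarLogLik(yt, b, s2, 1)$gBlup
    expect_lte(abs(g), abs(lastBig) + 1e-14)
    lastBig <- g
  }
  prior <- paretoPrior(0.2, 1, 100)  # sigma2 < sigma1
  upd <- snpUpdate(yt, b, prior, 1)
  expect_lte(abs(upd$gHatSmall), abs(upd$gHatBig))
})

test_that("prediction is the standardized-genotype effect sum", {
  dat <- toyTrainingData(n = 50, M = 12, seed = 71)
  prior <- paretoPrior(0.25, dat$vg, 12)
  fit <- fitMixP(dat$genotypes, dat$phenotypes, prior, dat$ve)
  # all-zero effects predict zero
  fit0 <- fit
  fit0@gHat[] <- 0
  expect_equal(unname(predict(fit0, dat$genotypes)), rep(0, 50))
  # single-marker effect of 1 returns that standardized column
  fit1 <- fit
  fit1@gHat[] <- 0
  fit1@gHat[3] <- 1
  expect_equal(predict(fit1, dat$genotypes),
               setNames(standardized(dat$genotypes)[, 3],
                        individualIds(dat$genotypes)))
  # duplicated evaluation individual gets an identical prediction
  dup <- dat$genotypes[c("id1", "id1", "id2"), ]
  pr <- predict(fit, dup)
  expect_equal(pr[1], pr[2], ignore_attr = TRUE)
  # marker mismatch is an error
  other <- GenotypeMatrix(toyDosages(10, 5, seed = 72))
  expect_error(predict(fit, other), "marker sets")
})

test_that("non-convergence within maxIter warns and flags the state", {
  dat <- toyTrainingData(n = 40, M = 30, seed = 81)
  prior <- paretoPrior(0.1, dat$vg, 30)
  expect_warning(
    fit <- fitMixP(dat$genotypes, dat$phenotypes, prior, dat$ve,
                   tol = 1e-12, maxIter = 2L),
    "did not converge")
  expect_false(fit@converged)
  expect_equal(fit@iterations, 2L)
})

test_that("the maintained residual matches its from-scratch recomputation", {
  dat <- toyTrainingData(n = 90, M = 60, seed = 91)
  prior <- paretoPrior(0.1, dat$vg, 60)
  fit <- fitMixP(dat$genotypes, dat$phenotypes, prior, dat$ve)
  B <- standardized(dat$genotypes)
  fresh <- unname(dat$phenotypes) - fit@mu - drop(B %*% markerEffects(fit))
  expect_equal(unname(fit@residual), unname(fresh), tolerance = 1e-8)
})
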