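#' Fit SNP-BLUP (GBLUP)
#'
#' Every marker effect receives the same normal prior with variance
#' \eqn{V_g/M}.  The `direct` solver solves the intercept-augmented
#' mixed-model equations
#' \deqn{\begin{pmatrix} n & 1'B \\ B'1 & B'B + \lambda I \end{pmatrix}
#'       \begin{pmatrix} \mu \\ \hat g \end{pmatrix} =
#'       \begin{pmatrix} 1'y \\ B'y \end{pmatrix}, \qquad
#'       \lambda = \sigma_e^2 M / V_g,}
#' exactly (dense Cholesky-backed `solve`); the `iterative` solver runs
#' per-marker Gauss-Seidel with the mean re-estimated once per sweep and the
#' same relative squared-change convergence rule as [fitMixP()].  The two
#' share a fixed point.  `"auto"` picks `direct` for \eqn{M \le 5000}.
#'
#' @param genotypes a [GenotypeMatrix-class] (training individuals).
#' @param phenotypes named numeric vector of records.
#' @param geneticVariance total genetic variance \eqn{V_g}.
#' @param residVar residual variance \eqn{\sigma_e^2}.
#' @param solver `"auto"`, `"direct"` or `"iterative"`.
#' @param tol convergence tolerance of the iterative solver.
#' @param maxIter sweep ceiling of the iterative solver.
#' @return a [GBLUPFit-class].
#' @export
fitGblup <- function(genotypes, phenotypes, geneticVariance, residVar,
                     solver = c("auto", "direct", "iterative"), tol = 1e-7,
                     maxIter = 5000L) {
  solver <- match.arg(solver)
  B <- standardized(genotypes)
  y <- alignPhenotypes(phenotypes, genotypes)
  if (any(!is.finite(B)) || any(!is.finite(y)))
    stop("non-finite genotype or phenotype input")
  if (geneticVariance <= 0 || residVar <= 0)
    stop("variance components must be positive")
  M <- ncol(B)
  if (solver == "auto") solver <- if (M <= 5000L) "direct" else "iterative"
  if (solver == "direct") {
    lambda <- residVar * M / geneticVariance
    n <- nrow(B)
    C <- rbind(cbind(n, t(colSums(B))),
               cbind(colSums(B), crossprod(B) + diag(lambda, M)))
    rhs <- c(sum(y), crossprod(B, y))
    sol <- solve(C, rhs)
    fit <- new("GBLUPFit", gHat = setNames(sol[-1], colnames(B)),
               mu = sol[1], solver = "direct", iterations = 0L,
               converged = TRUE, geneticVariance = geneticVariance,
               residVar = residVar)
  } else {
    res <- gblup_gs_cpp(B, y, geneticVariance / M, residVar, tol,
                        as.integer(maxIter), 25L)
    if (!res$converged)
      warning("iterative GBLUP did not converge in ", maxIter, " sweeps")
    fit <- new("GBLUPFit", gHat = setNames(res$g_hat, colnames(B)),
               mu = res$mu, solver = "iterative",
               iterations = as.integer(res$iterations),
               converged = res$converged,
               geneticVariance = geneticVariance, residVar = residVar)
  }
  fit
}

#' @describeIn GBLUPFit-class estimated marker effects.
#' @param x a GBLUPFit.
#' @export
setMethod("markerEffects", "GBLUPFit", function(x) x@gHat)

setMethod("show", "GBLUPFit", function(object) {
  cat("GBLUPFit (", object@solver, "):", length(object@gHat), "markers\n")
  if (object@solver == "iterative")
    cat("  ", if (object@converged) "converged" else "NOT converged",
        "in", object@iterations, "sweeps\n")
  cat("  mu =", signif(object@mu, 6), "\n")
})

#' @describeIn predict-MixPFit-method GBLUP predictions.
#' @export
setMethod("predict", "GBLUPFit", function(object, genotypes, ...) {
  predictGwebv(object@gHat, genotypes)
})

#' Fit a BayesB-style mixture model by Gibbs sampling
#'
#' Marker effects follow the same two-component normal mixture as MixP, but
#' the model is fitted by MCMC and the component variances are sampled
#' rather than fixed: each big-component marker carries a locus-specific
#' variance under a scaled inverse-\eqn{\chi^2}(`df`, \eqn{S_1}) prior, the
#' small component shares one variance under scaled
#' inverse-\eqn{\chi^2}(`df`, \eqn{S_2}).  The scales anchor the prior means
#' to the Pareto variances of [paretoPrior()]:
#' \eqn{S_k = \sigma_k^2 (\nu - 2)/\nu}.  Per sweep, each marker's component
#' indicator is drawn from the effect-integrated likelihood ratio
#' ([scalarLogLik()] identities), its effect from the Gaussian full
#' conditional, variances from their conjugate conditionals, and the mean
#' from its Gaussian full conditional.  The residual variance is known and
#' fixed.  Posterior means are taken over post-burn-in samples.
#'
#' @param genotypes a [GenotypeMatrix-class] (training individuals).
#' @param phenotypes named numeric vector of records.
#' @param pi proportion of markers in the big component, in (0, 1) (fixed,
#'   not sampled).
#' @param geneticVariance,residVar variance components.
#' @param nIter,nBurnin chain length (default 10000) and burn-in (3000).
#' @param df degrees of freedom of the inverse-\eqn{\chi^2} priors
#'   (default 4.2; must exceed 2 for the prior mean to exist).
#' @param seed mandatory RNG seed, stored in the result.
#' @param thin thinning interval of the recorded chain summary.
#' @param sigma1Sq,sigma2Sq optional prior-mean component variances,
#'   overriding the Pareto anchoring (used e.g. to study limiting cases).
#' @return a [BayesBFit-class]; slot `gSd` (via `fit@gSd`) holds the
#'   posterior standard deviation of each effect over kept samples.
#' @export
fitBayesB <- function(genotypes, phenotypes, pi, geneticVariance, residVar,
                      nIter = 10000L, nBurnin = 3000L, df = 4.2, seed,
                      thin = 10L, sigma1Sq = NULL, sigma2Sq = NULL) {
  if (missing(seed)) stop("a seed is required for the BayesB chain")
  if (pi <= 0 || pi >= 1) stop("pi must lie in (0, 1)")
  if (nBurnin >= nIter) stop("nBurnin must be smaller than nIter")
  if (df <= 2) stop("df must exceed 2")
  B <- standardized(genotypes)
  y <- alignPhenotypes(phenotypes, genotypes)
  M <- ncol(B)
  # component variances from the Pareto split at this pi (pi > 0.5 allowed
  # here: the sampler itself has no big/small semantics to preserve)
  s1 <- sigma1Sq %||% ((1 - pi) * geneticVariance / (pi * M))
  s2 <- sigma2Sq %||% (pi * geneticVariance / ((1 - pi) * M))
  res <- withSeed(as.integer(seed),
                  bayesb_cpp(B, y, pi, s1, s2, residVar, df,
                             as.integer(nIter), as.integer(nBurnin),
                             as.integer(thin)))
  chain <- res$chain
  colnames(chain) <- c("iteration", "mu", "sum_g_sq", "n_big")
  new("BayesBFit", gHat = setNames(res$g_hat, colnames(B)),
      gSd = setNames(res$g_sd, colnames(B)),
      probBig = setNames(res$prob_big, colnames(B)), mu = res$mu,
      nIter = as.integer(nIter), nBurnin = as.integer(nBurnin), df = df,
      pi = pi, seed = as.integer(seed), chain = chain)
}

#' @describeIn BayesBFit-class posterior-mean marker effects.
#' @param x a BayesBFit.
#' @export
setMethod("markerEffects", "BayesBFit", function(x) x@gHat)

#' @describeIn BayesBFit-class posterior big-component probabilities.
#' @export
setMethod("probBig", "BayesBFit", function(x) x@probBig)

setMethod("show", "BayesBFit", function(object) {
  cat("BayesBFit:", length(object@gHat), "markers, pi =", object@pi,
      ", df =", object@df, "\n")
  cat("  chain:", object@nIter, "iterations,", object@nBurnin,
      "burn-in, seed", object@seed, "\n")
})

#' @describeIn predict-MixPFit-method BayesB predictions.
#' @export
setMethod("predict", "BayesBFit", function(object, genotypes, ...) {
  predictGwebv(object@gHat, genotypes)
})

#' Write a thinned BayesB chain summary as TSV
#' @param fit a [BayesBFit-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeChainSummary <- function(fit, path) {
  write.table(as.data.frame(fit@chain), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
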