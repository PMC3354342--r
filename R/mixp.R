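#' Pareto-principle mixture prior
#'
#' Fixes both component variances of the two-normal mixture prior from the
#' mixture proportion alone: a fraction \eqn{\pi} of markers ('big' effects)
#' explains a fraction \eqn{1-\pi} of the genetic variance, so
#' \deqn{\sigma_1^2 = \frac{(1-\pi)V_g}{\pi M}, \qquad
#'       \sigma_2^2 = \frac{\pi V_g}{(1-\pi)M},}
#' which conserves \eqn{M(\pi\sigma_1^2 + (1-\pi)\sigma_2^2) = V_g}.
#' \eqn{\pi} is restricted to (0, 0.5]; beyond 0.5 the big/small labels
#' would invert.  At \eqn{\pi = 0.5} the prior equals the GBLUP prior.
#'
#' @param pi proportion of markers in the big-variance component, (0, 0.5].
#' @param geneticVariance total genetic variance \eqn{V_g > 0}.
#' @param nMarkers number of markers \eqn{M}.
#' @return a [MixturePrior-class].
#' @examples
#' paretoPrior(0.2, 1, 1000) # sigma1^2 = 0.004, sigma2^2 = 0.00025
#' @export
paretoPrior <- function(pi, geneticVariance, nMarkers) {
  if (length(pi) != 1 || !is.finite(pi) || pi <= 0 || pi > 0.5)
    stop("pi must be a single value in (0, 0.5]")
  if (geneticVariance <= 0) stop("geneticVariance must be positive")
  nMarkers <- as.integer(nMarkers)
  if (nMarkers < 1L) stop("need at least one marker")
  new("MixturePrior", pi = pi, geneticVariance = geneticVariance,
      nMarkers = nMarkers,
      sigma1Sq = (1 - pi) * geneticVariance / (pi * nMarkers),
      sigma2Sq = pi * geneticVariance / ((1 - pi) * nMarkers))
}

setMethod("show", "MixturePrior", function(object) {
  cat("MixturePrior: pi =", object@pi, ", Vg =", object@geneticVariance,
      ", M =", object@nMarkers, "\n")
  cat("  sigma1^2 =", signif(object@sigma1Sq, 6),
      " sigma2^2 =", signif(object@sigma2Sq, 6), "\n")
})

#' Single-SNP marginal log-likelihood and BLUP via scalar identities
#'
#' For the model \eqn{\tilde y = b g + e} with \eqn{g \sim N(0, \sigma^2)}
#' and \eqn{e \sim N(0, I\sigma_e^2)}, the marginal covariance is
#' \eqn{V = bb'\sigma^2 + I\sigma_e^2}.  Its determinant and quadratic form
#' reduce to scalars through the matrix determinant lemma and
#' Sherman-Morrison:
#' \eqn{|V| = (\sigma_e^2)^n (b'b\,\sigma^2/\sigma_e^2 + 1)} and
#' \eqn{\tilde y'V^{-1}\tilde y = (\tilde y'\tilde y - \tilde y'b\,\hat g)/\sigma_e^2}
#' with \eqn{\hat g = b'\tilde y/(b'b + \sigma_e^2/\sigma^2)}, so no
#' \eqn{n \times n} matrix is ever formed.  The returned value is the exact
#' multivariate normal log density (constant included), so the same
#' constant is shared by both mixture components and cancels in their ratio.
#' `sigmaSq = 0` is handled as the limit \eqn{V = I\sigma_e^2}, `gBlup = 0`.
#'
#' @param yTilde numeric vector of corrected records.
#' @param b numeric vector of standardized genotypes (same length).
#' @param sigmaSq prior variance of the effect, \eqn{\ge 0}.
#' @param residVar residual variance \eqn{\sigma_e^2 > 0}.
#' @return list with `loglik` and `gBlup`.
#' @export
scalarLogLik <- function(yTilde, b, sigmaSq, residVar) {
  if (length(yTilde) != length(b)) stop("yTilde and b lengths differ")
  if (residVar <= 0) stop("residVar must be positive")
  if (sigmaSq < 0) stop("sigmaSq must be non-negative")
  n <- length(yTilde)
  btb <- sum(b * b)
  bty <- sum(b * yTilde)
  yty <- sum(yTilde * yTilde)
  gBlup <- if (sigmaSq == 0 || btb == 0) 0 else bty / (btb + residVar / sigmaSq)
  loglik <- -0.5 * n * log(2 * pi) - 0.5 *
    (n * log(residVar) + log(btb * sigmaSq / residVar + 1)) -
    0.5 * (yty - bty * gBlup) / residVar
  list(loglik = loglik, gBlup = gBlup)
}

#' Posterior-mean update for one SNP under the mixture prior
#'
#' The conditional expectation of a single marker effect given the records
#' corrected for all other markers: BLUP estimates are computed under each
#' component variance, and combined with weights equal to the posterior
#' component probabilities,
#' \deqn{\hat g_i = P_{1i}\,\hat g_{1i} + (1 - P_{1i})\,\hat g_{2i}, \qquad
#'   P_{1i} = \frac{\pi L_{1i}}{\pi L_{1i} + (1-\pi)L_{2i}},}
#' with the likelihood ratio evaluated in log space (exponent clamped at
#' ±700) to avoid underflow at realistic record counts.
#'
#' @param yTilde corrected records \eqn{\tilde y_i} for this SNP.
#' @param b standardized genotype column.
#' @param prior a [MixturePrior-class].
#' @param residVar residual variance.
#' @return list with `gHatBig`, `gHatSmall`, `loglikBig`, `loglikSmall`,
#'   `posteriorBig` and the combined `gHat`.
#' @export
snpUpdate <- function(yTilde, b, prior, residVar) {
  big <- scalarLogLik(yTilde, b, prior@sigma1Sq, residVar)
  small <- scalarLogLik(yTilde, b, prior@sigma2Sq, residVar)
  z <- log1p(-prior@pi) - log(prior@pi) + small$loglik - big$loglik
  z <- min(max(z, -700), 700)
  p1 <- 1 / (1 + exp(z))
  g <- p1 * big$gBlup + (1 - p1) * small$gBlup
  if (!is.finite(g)) stop("non-finite SNP update")
  list(gHatBig = big$gBlup, gHatSmall = small$gBlup,
       loglikBig = big$loglik, loglikSmall = small$loglik,
       posteriorBig = p1, gHat = g)
}

#' Fit MixP by iterative conditional expectation
#'
#' Cycles over markers in fixed ascending order, replacing each effect by
#' its posterior mean given the current estimates of all others
#' ([snpUpdate()]), with the overall mean re-estimated once per sweep before
#' the marker updates.  Convergence is declared when the sum of squared
#' changes falls below `tol` times the sum of squared solutions (the
#' criterion is treated as unmet while all solutions are zero).  The
#' residual is maintained incrementally and recomputed from scratch every 25
#' sweeps and at convergence to bound floating-point drift.
#'
#' @param genotypes a [GenotypeMatrix-class] (training individuals).
#' @param phenotypes named numeric vector of records; names are matched
#'   against `individualIds(genotypes)`.
#' @param prior a [MixturePrior-class]; its `nMarkers` must equal the marker
#'   count of `genotypes`.
#' @param residVar residual variance \eqn{\sigma_e^2}.
#' @param tol relative convergence tolerance (default `1e-5`).
#' @param maxIter sweep ceiling (default 1000); reaching it yields a warning
#'   and `converged = FALSE`, not an error.
#' @return a [MixPFit-class].
#' @examples
#' set.seed(1)
#' d <- matrix(rbinom(300, 2, 0.4), 30, 10)
#' g <- GenotypeMatrix(d)
#' y <- setNames(rnorm(30), individualIds(g))
#' fitMixP(g, y, paretoPrior(0.2, 1, 10), residVar = 1)
#' @export
fitMixP <- function(genotypes, phenotypes, prior, residVar, tol = 1e-5,
                    maxIter = 1000L) {
  B <- standardized(genotypes)
  y <- alignPhenotypes(phenotypes, genotypes)
  if (prior@nMarkers != ncol(B))
    stop("prior built for ", prior@nMarkers, " markers but genotypes have ",
         ncol(B))
  if (residVar <= 0) stop("residVar must be positive")
  res <- mixp_fit_cpp(B, y, prior@pi, prior@sigma1Sq, prior@sigma2Sq,
                      residVar, tol, as.integer(maxIter), 25L)
  if (!res$converged)
    warning("MixP did not converge in ", maxIter, " sweeps")
  new("MixPFit",
      gHat = setNames(res$g_hat, colnames(B)), mu = res$mu,
      probBig = setNames(res$prob_big, colnames(B)),
      residual = setNames(res$residual, rownames(B)),
      iterations = as.integer(res$iterations), converged = res$converged,
      changeSqSum = res$change_sq_sum, solutionSqSum = res$solution_sq_sum,
      prior = prior, residVar = residVar, tol = tol)
}

alignPhenotypes <- function(phenotypes, genotypes) {
  ids <- individualIds(genotypes)
  if (is.null(names(phenotypes))) {
    if (length(phenotypes) != length(ids))
      stop("unnamed phenotypes must match the genotype row count")
    return(as.numeric(phenotypes))
  }
  miss <- setdiff(ids, names(phenotypes))
  if (length(miss))
    stop("no phenotype for individual(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  as.numeric(phenotypes[ids])
}

#' @describeIn MixPFit-class estimated marker effects.
#' @param x a MixPFit.
#' @export
setMethod("markerEffects", "MixPFit", function(x) x@gHat)

#' @describeIn MixPFit-class posterior big-component probabilities.
#' @export
setMethod("probBig", "MixPFit", function(x) x@probBig)

setMethod("show", "MixPFit", function(object) {
  cat("MixPFit:", length(object@gHat), "markers, pi =", object@prior@pi, "\n")
  cat("  ", if (object@converged) "converged" else "NOT converged", "in",
      object@iterations, "sweeps (tol", object@tol, ")\n")
  cat("  mu =", signif(object@mu, 6), ", mean P(big) =",
      signif(mean(object@probBig), 4), "\n")
})

#' Predict genome-wide breeding values
#'
#' \eqn{GWEBV_j = \sum_i b_{ji} \hat g_i} over the standardized evaluation
#' genotypes.  The evaluation [GenotypeMatrix-class] must carry the same
#' markers (and, for meaningful results, the same allele-frequency scaling —
#' use row subsetting of one full GenotypeMatrix).  The overall mean is not
#' added: predictions are breeding values on the deviation scale, which is
#' what rankings and accuracy correlations use.
#'
#' @param object a [MixPFit-class], [GBLUPFit-class] or [BayesBFit-class].
#' @param genotypes a [GenotypeMatrix-class] of evaluation individuals.
#' @param ... unused.
#' @return named numeric vector of GWEBV.
#' @export
setMethod("predict", "MixPFit", function(object, genotypes, ...) {
  predictGwebv(object@gHat, genotypes)
})

predictGwebv <- function(gHat, genotypes) {
  B <- standardized(genotypes)
  if (!identical(colnames(B), names(gHat)))
    stop("marker sets of fit and genotypes do not match")
  setNames(drop(B %*% gHat), rownames(B))
}

#' Write estimated effects as TSV
#'
#' Columns `marker_id`, `g_hat`, `posterior_prob_big` (the latter `NA` for
#' fits without component probabilities).
#'
#' @param fit a [MixPFit-class], [GBLUPFit-class] or [BayesBFit-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEffects <- function(fit, path) {
  g <- markerEffects(fit)
  p <- if (is(fit, "GBLUPFit")) rep(NA_real_, length(g)) else probBig(fit)
  write.table(data.frame(marker_id = names(g), g_hat = unname(g),
                         posterior_prob_big = unname(p)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
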