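#' @import methods
#' @importFrom stats var cor sd median rnorm rexp runif integrate setNames
#' @importFrom utils read.table write.table head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib MixPareto, .registration = TRUE
NULL

#' Standardized SNP genotype matrix
#'
#' Holds allele dosages (counts of the '1' allele, 0/1/2, possibly `NA`),
#' per-marker allele frequencies and the standardized design matrix used by
#' all estimators.  Column \eqn{i} of the standardized matrix takes the
#' values \eqn{-2p_i/\sqrt{2p_i(1-p_i)}}, \eqn{(1-2p_i)/\sqrt{2p_i(1-p_i)}}
#' and \eqn{2(1-p_i)/\sqrt{2p_i(1-p_i)}} at dosages 0, 1 and 2, so that a
#' column in Hardy-Weinberg proportions has mean 0 and variance 1.
#' Monomorphic markers are removed before standardization (their names are
#' kept in `droppedMarkers`); missing dosages are mean-imputed (to
#' \eqn{2p_i}) in the standardized matrix only.
#'
#' @slot dosages numeric matrix, individuals x markers, entries in
#'   \{0, 1, 2, NA\} (raw, un-imputed).
#' @slot alleleFreq numeric vector of allele frequencies \eqn{p_i \in (0,1)}.
#' @slot standardized numeric matrix of standardized genotypes.
#' @slot droppedMarkers character vector of removed marker ids.
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosages = "matrix", alleleFreq = "numeric",
                 standardized = "matrix", droppedMarkers = "character"),
  validity = function(object) {
    d <- object@dosages
    msg <- character()
    if (!all(is.na(d) | (d >= 0 & d <= 2)))
      msg <- c(msg, "dosages must lie in [0, 2] or be NA")
    if (length(object@alleleFreq) != ncol(d))
      msg <- c(msg, "alleleFreq length must equal the number of markers")
    if (any(object@alleleFreq <= 0 | object@alleleFreq >= 1))
      msg <- c(msg, "allele frequencies must be strictly inside (0, 1)")
    if (!identical(dim(object@standardized), dim(d)))
      msg <- c(msg, "standardized matrix must match dosage dimensions")
    if (length(msg)) msg else TRUE
  })

#' Two-component mixture prior with Pareto-principle variances
#'
#' A proportion \eqn{\pi} of the markers carries the 'big' effects with
#' variance \eqn{\sigma_1^2 = (1-\pi)V_g/(\pi M)}; the remainder carries the
#' 'small' effects with variance \eqn{\sigma_2^2 = \pi V_g/((1-\pi) M)}.
#' These satisfy \eqn{M(\pi\sigma_1^2 + (1-\pi)\sigma_2^2) = V_g}, so the
#' prior is fully determined by \eqn{\pi}, the total genetic variance and
#' the marker count.  At \eqn{\pi = 0.5} both variances equal \eqn{V_g/M}
#' and the prior collapses to the SNP-BLUP (GBLUP) prior.
#'
#' @slot pi mixture proportion, in (0, 0.5].
#' @slot geneticVariance total genetic variance \eqn{V_g}.
#' @slot nMarkers number of markers \eqn{M}.
#' @slot sigma1Sq,sigma2Sq component variances.
#' @aliases MixturePrior-class
#' @exportClass MixturePrior
setClass("MixturePrior",
  representation(pi = "numeric", geneticVariance = "numeric",
                 nMarkers = "integer", sigma1Sq = "numeric",
                 sigma2Sq = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@pi <= 0 || object@pi > 0.5)
      msg <- c(msg, "pi must lie in (0, 0.5]")
    if (object@geneticVariance <= 0)
      msg <- c(msg, "genetic variance must be positive")
    if (object@nMarkers < 1L) msg <- c(msg, "need at least one marker")
    vg <- object@nMarkers * (object@pi * object@sigma1Sq +
                             (1 - object@pi) * object@sigma2Sq)
    if (abs(vg - object@geneticVariance) >
        1e-8 * max(1, object@geneticVariance))
      msg <- c(msg, "component variances do not conserve Vg")
    if (length(msg)) msg else TRUE
  })

#' Pedigree with genotyping flags and training/evaluation roles
#'
#' An ordered table of individuals with sire/dam links (`NA` for unknown
#' founder slots).  The order is topological: every parent appears before
#' its offspring.
#'
#' @slot records data.frame with columns `id`, `sire`, `dam` (character,
#'   `NA` = unknown), `genotyped` (logical) and `role` (one of
#'   `"training"`, `"evaluation"`, `"none"`).
#' @aliases Pedigree-class
#' @exportClass Pedigree
setClass("Pedigree",
  representation(records = "data.frame"),
  validity = function(object) {
    r <- object@records
    need <- c("id", "sire", "dam", "genotyped", "role")
    if (!all(need %in% names(r)))
      return(paste("records must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(r$id)) return("duplicated individual ids")
    if (!all(r$role %in% c("training", "evaluation", "none")))
      return("role must be training, evaluation or none")
    pos <- seq_len(nrow(r))
    names(pos) <- r$id
    for (col in c("sire", "dam")) {
      p <- r[[col]]
      known <- !is.na(p)
      if (any(!p[known] %in% r$id))
        return(sprintf("%s refers to an unlisted individual", col))
      if (any(pos[p[known]] >= pos[known]))
        return("pedigree is not topologically sorted (parent after offspring)")
    }
    TRUE
  })

#' Converged state of the iterative conditional expectation solver
#'
#' @slot gHat named numeric vector of posterior-mean marker effects.
#' @slot mu overall mean.
#' @slot probBig per-marker posterior probability of the big component.
#' @slot residual training residual \eqn{y - 1\mu - B\hat g}.
#' @slot iterations number of sweeps performed.
#' @slot converged whether the relative squared-change criterion was met.
#' @slot changeSqSum,solutionSqSum convergence bookkeeping at the last sweep.
#' @slot prior the [MixturePrior-class] used.
#' @slot residVar residual variance \eqn{\sigma_e^2}.
#' @slot tol convergence tolerance.
#' @aliases MixPFit-class
#' @exportClass MixPFit
setClass("MixPFit",
  representation(gHat = "numeric", mu = "numeric", probBig = "numeric",
                 residual = "numeric", iterations = "integer",
                 converged = "logical", changeSqSum = "numeric",
                 solutionSqSum = "numeric", prior = "MixturePrior",
                 residVar = "numeric", tol = "numeric"),
  validity = function(object) {
    if (any(object@probBig < 0 | object@probBig > 1))
      return("posterior probabilities must lie in [0, 1]")
    if (length(object@probBig) != length(object@gHat))
      return("probBig and gHat lengths differ")
    TRUE
  })

#' SNP-BLUP (GBLUP) fit
#'
#' @slot gHat named numeric vector of marker effects.
#' @slot mu overall mean.
#' @slot solver `"direct"` or `"iterative"`.
#' @slot iterations sweep count (0 for the direct solver).
#' @slot converged logical (always `TRUE` for the direct solver).
#' @slot geneticVariance,residVar variance components used.
#' @aliases GBLUPFit-class
#' @exportClass GBLUPFit
setClass("GBLUPFit",
  representation(gHat = "numeric", mu = "numeric", solver = "character",
                 iterations = "integer", converged = "logical",
                 geneticVariance = "numeric", residVar = "numeric"))

#' BayesB-style MCMC fit
#'
#' @slot gHat posterior-mean marker effects over kept samples.
#' @slot gSd posterior standard deviation of each effect over kept samples.
#' @slot probBig posterior probability of the big component per marker.
#' @slot mu posterior-mean overall mean.
#' @slot nIter,nBurnin chain length and burn-in.
#' @slot df degrees of freedom of the scaled inverse-chi-squared priors.
#' @slot pi mixture proportion (fixed, not sampled).
#' @slot seed RNG seed used for the chain.
#' @slot chain thinned chain summary (iteration, mu, sum of squared effects,
#'   number of markers currently in the big component).
#' @aliases BayesBFit-class
#' @exportClass BayesBFit
setClass("BayesBFit",
  representation(gHat = "numeric", gSd = "numeric", probBig = "numeric",
                 mu = "numeric", nIter = "integer", nBurnin = "integer",
                 df = "numeric", pi = "numeric", seed = "integer",
                 chain = "matrix"),
  validity = function(object) {
    if (any(object@probBig < 0 | object@probBig > 1))
      return("posterior inclusion probabilities must lie in [0, 1]")
    if (any(!is.finite(object@gHat))) return("non-finite effect estimates")
    TRUE
  })
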