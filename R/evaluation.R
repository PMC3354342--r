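#' Prediction accuracy
#'
#' Pearson correlation between predicted breeding values and the truth
#' (true breeding values in simulation, phenotypes in cross-validation).
#' Constant vectors make the correlation undefined and raise an error
#' rather than silently returning 0.
#'
#' @param gwebv,truth aligned numeric vectors of length >= 3.
#' @return the correlation coefficient.
#' @examples
#' accuracy(c(1, 2, 3), c(1, 2, 4))
#' @export
accuracy <- function(gwebv, truth) {
  if (length(gwebv) != length(truth)) stop("vector lengths differ")
  if (length(gwebv) < 3) stop("need at least 3 observations")
  if (sd(gwebv) == 0 || sd(truth) == 0)
    stop("accuracy undefined for a constant vector")
  cor(gwebv, truth)
}

#' Run a replicated simulation scenario
#'
#' For each replicate: sample marker/QTL sets from the (shared) historical
#' pool, gene-drop through the (shared) pedigree, simulate the trait, fit
#' each requested method on the training individuals using the simulated
#' variance components, predict the evaluation individuals, and score the
#' correlation with true breeding values.  MixP and BayesB use
#' \eqn{\pi = N_{QTL}/N_{mkr}}.  Per-replicate seeds are derived from the
#' master seed; a degenerate replicate (zero realized genetic variance) is
#' redrawn with a derived seed, at most 5 times.
#'
#' @param config a [simConfig()] list.
#' @param methods subset of `c("mixp", "gblup", "bayesb")`.
#' @param nReplicates number of replicates (default 20).
#' @param seed master seed.
#' @param pool optional shared `HaplotypePool` (simulated once otherwise).
#' @param pedigree optional shared [Pedigree-class] (defaults to
#'   [generatePedigree()] defaults).
#' @param bayesbIter,bayesbBurnin chain settings for the BayesB baseline.
#' @param mixpIterations if `TRUE`, also record per-replicate MixP sweep
#'   counts (`$mixpSweeps`) and convergence flags (`$mixpConverged`).
#' @return an `AccuracyReport`: list with a long `replicates` data.frame
#'   (method, replicate, accuracy) and a `summary` data.frame (method,
#'   mean, stdError, n).
#' @export
runScenario <- function(config, methods = c("mixp", "gblup"),
                        nReplicates = 20L, seed = 1L, pool = NULL,
                        pedigree = NULL, bayesbIter = 10000L,
                        bayesbBurnin = 3000L, mixpIterations = FALSE) {
  methods <- match.arg(methods, c("mixp", "gblup", "bayesb"),
                       several.ok = TRUE)
  seeds <- deriveSeeds(seed, 2L + nReplicates)
  if (is.null(pool))
    pool <- simulateIdealPopulation(config, seed = seeds[1])
  if (is.null(pedigree)) pedigree <- generatePedigree(seed = seeds[2])
  r <- pedRecords(pedigree)
  trainIds <- r$id[r$role == "training"]
  evalIds <- r$id[r$role == "evaluation"]
  rows <- list()
  sweeps <- integer(0)
  convFlags <- logical(0)
  for (rep in seq_len(nReplicates)) {
    repSeed <- seeds[2L + rep]
    sim <- NULL
    for (try in 0:5) {
      sim <- tryCatch(
        simulateDataset(config, seed = repSeed + try, pool = pool,
                        pedigree = pedigree),
        error = function(e) {
          if (grepl("degenerate trait", conditionMessage(e))) NULL
          else stop(e)
        })
      if (!is.null(sim)) break
      message("replicate ", rep, ": degenerate trait, redrawing")
    }
    if (is.null(sim)) stop("replicate ", rep, " failed after 5 redraws")
    gTrain <- sim$genotypes[trainIds, ]
    gEval <- sim$genotypes[evalIds, ]
    vg <- sim$trait$realizedVg
    ve <- sim$trait$residVar
    tbvEval <- sim$trait$trueBv[evalIds]
    for (m in methods) {
      fit <- switch(m,
        mixp = fitMixP(gTrain, sim$phenotypes,
                       paretoPrior(min(sim$piNominal, 0.5), vg,
                                   ncol(dosages(gTrain))), ve),
        gblup = fitGblup(gTrain, sim$phenotypes, vg, ve),
        bayesb = fitBayesB(gTrain, sim$phenotypes, sim$piNominal, vg, ve,
                           nIter = bayesbIter, nBurnin = bayesbBurnin,
                           seed = repSeed))
      if (m == "mixp" && mixpIterations) {
        sweeps <- c(sweeps, fit@iterations)
        convFlags <- c(convFlags, fit@converged)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(method = m, replicate = rep,
                   accuracy = accuracy(predict(fit, gEval), tbvEval))
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$method), function(d)
    data.frame(method = d$method[1], mean = mean(d$accuracy),
               stdError = sd(d$accuracy) / sqrt(nrow(d)), n = nrow(d))))
  rownames(summ) <- NULL
  out <- list(replicates = reps, summary = summ, config = config)
  if (mixpIterations) {
    out$mixpSweeps <- sweeps
    out$mixpConverged <- convFlags
  }
  structure(out, class = "AccuracyReport")
}

#' @export
print.AccuracyReport <- function(x, ...) {
  cat("AccuracyReport:", max(x$replicates$replicate), "replicates\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Pooled standard error of the difference of two per-method means.
pooledSE <- function(report, m1, m2) {
  s <- report$summary
  sqrt(s$stdError[s$method == m1]^2 + s$stdError[s$method == m2]^2)
}

#' Cross-validated grid search for the mixture proportion
#'
#' Ten-replicate, ten-fold cross-validation by default: each replicate
#' randomly partitions the individuals into `nFolds` groups of as equal
#' size as possible; each fold is held out in turn, MixP is fitted on the
#' remainder with \eqn{V_g = h^2 \mathrm{var}(y_{train})} and
#' \eqn{\sigma_e^2 = (1 - h^2)\mathrm{var}(y_{train})}, and the held-out
#' criterion is the correlation between GWEBV and phenotype.  Per-fold
#' correlations are averaged across folds and replicates for every
#' \eqn{\pi} on the grid.
#'
#' @param genotypes a [GenotypeMatrix-class] (all individuals).
#' @param phenotypes named numeric vector covering all individuals.
#' @param heritability trait heritability \eqn{h^2} used to split the
#'   phenotypic variance.
#' @param piGrid increasing grid of mixture proportions (default 0.01 to
#'   0.50 in steps of 0.01).
#' @param nFolds folds per replicate (default 10).
#' @param nReplicates partition replicates (default 10).
#' @param seed RNG seed for the partitions.
#' @param tol,maxIter passed to [fitMixP()].
#' @return a `CVGrid`: list with `piGrid`, `meanCorrelation`, `bestPi`
#'   (argmax), `foldAssignments` (replicate x individual matrix) and the
#'   full `grid` data.frame.
#' @export
cvGridSearch <- function(genotypes, phenotypes, heritability,
                         piGrid = seq(0.01, 0.50, by = 0.01), nFolds = 10L,
                         nReplicates = 10L, seed = 1L, tol = 1e-5,
                         maxIter = 1000L) {
  if (nFolds < 2) stop("need at least 2 folds")
  if (is.unsorted(piGrid, strictly = TRUE))
    stop("piGrid must be strictly increasing")
  if (any(piGrid <= 0 | piGrid > 0.5)) stop("piGrid values must be in (0, 0.5]")
  ids <- individualIds(genotypes)
  y <- alignPhenotypes(phenotypes, genotypes)
  names(y) <- ids
  n <- length(ids)
  M <- ncol(dosages(genotypes))
  seeds <- deriveSeeds(seed, nReplicates)
  folds <- matrix(0L, nReplicates, n, dimnames = list(NULL, ids))
  acc <- array(NA_real_, c(length(piGrid), nReplicates, nFolds))
  for (repl in seq_len(nReplicates)) {
    fold <- withSeed(seeds[repl],
                     sample(rep_len(seq_len(nFolds), n)))
    folds[repl, ] <- fold
    for (k in seq_len(nFolds)) {
      testIds <- ids[fold == k]
      trainIds <- ids[fold != k]
      yTrain <- y[trainIds]
      if (sd(y[testIds]) == 0) {
        warning("fold ", k, " of replicate ", repl,
                " has constant phenotype; skipped")
        next
      }
      vy <- var(yTrain)
      vg <- heritability * vy
      ve <- (1 - heritability) * vy
      gTrain <- genotypes[trainIds, ]
      gTest <- genotypes[testIds, ]
      for (p in seq_along(piGrid)) {
        fit <- suppressWarnings(
          fitMixP(gTrain, yTrain, paretoPrior(piGrid[p], vg, M), ve,
                  tol = tol, maxIter = maxIter))
        acc[p, repl, k] <- accuracy(predict(fit, gTest), y[testIds])
      }
    }
  }
  meanCor <- apply(acc, 1, mean, na.rm = TRUE)
  structure(list(piGrid = piGrid, meanCorrelation = meanCor,
                 bestPi = piGrid[which.max(meanCor)],
                 foldAssignments = folds,
                 grid = data.frame(pi = piGrid,
                                   mean_correlation = meanCor)),
            class = "CVGrid")
}

#' @export
print.CVGrid <- function(x, ...) {
  cat("CVGrid:", length(x$piGrid), "pi values, best pi =", x$bestPi,
      "(mean r =", signif(max(x$meanCorrelation), 4), ")\n")
  invisible(x)
}

#' Expected accuracy of genome-wide prediction
#'
#' Deterministic accuracy formula
#' \eqn{r = \sqrt{N h^2 / (N h^2 + 4 N_e L v)}}, where \eqn{4 N_e L} is the
#' number of chromosome segments and \eqn{v} the ratio of effective to
#' actual segments, so \eqn{4 N_e L v} is the effective number of
#' independent segments.  The formula is invariant to scaling \eqn{h^2} and
#' \eqn{L} down by a common factor — the argument behind simulating a
#' single chromosome with a per-chromosome heritability.
#'
#' @param nTraining number of training records \eqn{N}.
#' @param heritability \eqn{h^2 \in (0, 1]}.
#' @param effectiveSize \eqn{N_e}.
#' @param genomeLength genome size \eqn{L} in Morgan.
#' @param segmentRatio \eqn{v > 0}.
#' @return the expected accuracy \eqn{r}.
#' @export
expectedAccuracy <- function(nTraining, heritability, effectiveSize,
                             genomeLength, segmentRatio = 1) {
  stopifnot(nTraining > 0, heritability > 0, heritability <= 1,
            effectiveSize > 0, genomeLength > 0, segmentRatio > 0)
  nh2 <- nTraining * heritability
  sqrt(nh2 / (nh2 + 4 * effectiveSize * genomeLength * segmentRatio))
}

#' Write an accuracy report as TSV
#'
#' The per-replicate table plus a `.summary.tsv` companion.
#'
#' @param report an `AccuracyReport`.
#' @param path output path of the per-replicate table.
#' @return `path`, invisibly.
#' @export
writeAccuracyReport <- function(report, path) {
  write.table(report$replicates, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$summary, sub("\\.tsv$", "", path) |>
                paste0(".summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
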