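#' Simulation configuration
#'
#' Bundles the parameters of the historical ideal population, locus
#' sampling and trait model.  Defaults are desk-scale: an effective size of
#' 100 run for 800 generations with the mutation rate doubled to
#' \eqn{2\times 10^{-8}} per bp, which preserves the population mutation
#' parameter \eqn{\theta = 4 N_e \mu L_{bp} = 800} of the full-scale setting
#' (effective size 200, 10000 generations, \eqn{\mu = 10^{-8}}); the latter
#' is available by passing those values explicitly.  One chromosome of 1
#' Morgan / \eqn{10^8} bp, per-chromosome heritability, Laplace(0, 1) QTL
#' effects, MAF threshold 0.05.
#'
#' @param effectiveSize historical effective population size \eqn{N_e}.
#' @param nGenerationsHistory generations simulated to reach mutation-drift
#'   balance.
#' @param genomeLengthBp physical genome length in bp.
#' @param genomeLengthMorgan map length in Morgan.
#' @param mutationRate per-bp, per-meiosis mutation rate.
#' @param mafThreshold minimum minor-allele frequency for marker/QTL
#'   sampling, in (0, 0.5).
#' @param nQtl number of QTL.
#' @param nMarkers number of markers.
#' @param h2Chr per-chromosome heritability in (0, 1).
#' @param laplaceScale scale of the Laplace QTL-effect distribution.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(effectiveSize = 100L, nGenerationsHistory = 800L,
                      genomeLengthBp = 1e8, genomeLengthMorgan = 1,
                      mutationRate = 2e-8, mafThreshold = 0.05,
                      nQtl = 30L, nMarkers = 1500L, h2Chr = 0.03,
                      laplaceScale = 1) {
  stopifnot(effectiveSize >= 2, nGenerationsHistory >= 1,
            genomeLengthBp > 0, genomeLengthMorgan >= 0, mutationRate >= 0,
            mafThreshold > 0, mafThreshold < 0.5, nQtl >= 1, nMarkers >= 1,
            h2Chr > 0, h2Chr < 1, laplaceScale > 0)
  structure(list(effectiveSize = as.integer(effectiveSize),
                 nGenerationsHistory = as.integer(nGenerationsHistory),
                 genomeLengthBp = genomeLengthBp,
                 genomeLengthMorgan = genomeLengthMorgan,
                 mutationRate = mutationRate, mafThreshold = mafThreshold,
                 nQtl = as.integer(nQtl), nMarkers = as.integer(nMarkers),
                 h2Chr = h2Chr, laplaceScale = laplaceScale),
            class = "SimConfig")
}

#' Forward-simulate an ideal population to mutation-drift balance
#'
#' Neutral Wright-Fisher forward simulation of \eqn{2 N_e} haplotypes:
#' random mating with replacement, Haldane (Poisson, no-interference)
#' recombination with expectation `genomeLengthMorgan` crossovers per
#' gamete, and Poisson infinite-sites mutation on the integer position grid
#' `1..genomeLengthBp`.  Fixed and lost sites are pruned each generation.
#' Deterministic given `seed`.
#'
#' @param config a [simConfig()] list.
#' @param seed optional RNG seed.
#' @return a `HaplotypePool` list with `haplotypes` (list of sorted integer
#'   position vectors), `positions`, `freq` (derived-allele frequencies of
#'   segregating sites) and the generating `config`.
#' @export
simulateIdealPopulation <- function(config = simConfig(), seed = NULL) {
  pool <- withSeed(seed, sim_pool_cpp(config$effectiveSize,
                                      config$nGenerationsHistory,
                                      config$genomeLengthMorgan,
                                      config$mutationRate * config$genomeLengthBp,
                                      config$genomeLengthBp))
  structure(list(haplotypes = pool$haplotypes,
                 positions = pool$positions,
                 freq = pool$counts / (2 * config$effectiveSize),
                 config = config),
            class = "HaplotypePool")
}

#' @export
print.HaplotypePool <- function(x, ...) {
  cat("HaplotypePool:", length(x$haplotypes), "haplotypes,",
      length(x$positions), "segregating sites\n")
  invisible(x)
}

#' Sample marker and QTL positions from a haplotype pool
#'
#' Positions qualify when their minor-allele frequency (folded spectrum)
#' meets the threshold.  QTL are drawn first, uniformly without
#' replacement; markers are then drawn from the remaining qualifying sites,
#' so the two sets are disjoint.
#'
#' @param pool a `HaplotypePool`.
#' @param config a [simConfig()] list (uses `nQtl`, `nMarkers`,
#'   `mafThreshold`).
#' @param seed optional RNG seed.
#' @return list with sorted `markerPositions` and `qtlPositions`.
#' @export
sampleLoci <- function(pool, config = pool$config, seed = NULL) {
  maf <- pmin(pool$freq, 1 - pool$freq)
  ok <- pool$positions[maf >= config$mafThreshold]
  need <- config$nQtl + config$nMarkers
  if (length(ok) < need)
    stop("only ", length(ok), " sites with MAF >= ", config$mafThreshold,
         " but ", need, " needed; simulate a longer history or lower ",
         "the threshold")
  withSeed(seed, {
    qtl <- sample(ok, config$nQtl)
    mkr <- sample(setdiff(ok, qtl), config$nMarkers)
    list(markerPositions = sort(mkr), qtlPositions = sort(qtl))
  })
}

#' Generate a layered synthetic pedigree
#'
#' Emulates the shape of a large dairy-cattle pedigree: generation 0 are
#' founders with unknown parents; each later generation draws sire and dam
#' uniformly from the previous generation.  The last `nGenotyped`
#' individuals (pedigree order) are flagged genotyped; of these, the oldest
#' `nTraining` get role `training` and the youngest `nEvaluation` get
#' `evaluation`.  Defaults mirror a population of 19523 individuals over 8
#' generations with 2165 genotyped bulls split 1915 / 250.
#'
#' @param nTotal total individuals.
#' @param nGenerations number of generations (layers).
#' @param nGenotyped,nTraining,nEvaluation counts; must satisfy
#'   `nTraining + nEvaluation <= nGenotyped <= nTotal`.
#' @param seed optional RNG seed.
#' @return a [Pedigree-class].
#' @export
generatePedigree <- function(nTotal = 19523L, nGenerations = 8L,
                             nGenotyped = 2165L, nTraining = 1915L,
                             nEvaluation = 250L, seed = NULL) {
  nTotal <- as.integer(nTotal)
  nGenerations <- as.integer(nGenerations)
  if (nTraining + nEvaluation > nGenotyped || nGenotyped > nTotal)
    stop("need nTraining + nEvaluation <= nGenotyped <= nTotal")
  sizes <- rep(nTotal %/% nGenerations, nGenerations)
  extra <- nTotal %% nGenerations
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (any(sizes < 1L)) stop("more generations than individuals")
  id <- paste0("ind", seq_len(nTotal))
  sire <- dam <- rep(NA_character_, nTotal)
  offset <- cumsum(c(0L, sizes))
  withSeed(seed, {
    for (g in seq_len(nGenerations - 1L)) {
      prev <- id[(offset[g] + 1L):offset[g + 1L]]
      cur <- (offset[g + 1L] + 1L):offset[g + 2L]
      sire[cur] <- sample(prev, length(cur), replace = TRUE)
      dam[cur] <- sample(prev, length(cur), replace = TRUE)
    }
  })
  genotyped <- rep(FALSE, nTotal)
  genotyped[(nTotal - nGenotyped + 1L):nTotal] <- TRUE
  role <- rep("none", nTotal)
  gidx <- which(genotyped)
  role[gidx[seq_len(nTraining)]] <- "training"
  role[utils::tail(gidx, nEvaluation)] <- "evaluation"
  Pedigree(id, sire, dam, genotyped, role)
}

#' Gene-drop pool haplotypes through a pedigree
#'
#' Founders receive two haplotypes drawn uniformly without replacement from
#' the final-generation pool (with replacement once the pool is exhausted,
#' reported via a message); every non-founder receives one recombinant
#' gamete from each parent (Poisson crossovers, Haldane model).  No new
#' mutation occurs.  A non-founder with a single unknown parent gets, for
#' the unknown slot, a gamete from a freshly drawn founder haplotype pair.
#' Only the requested marker and QTL positions are tracked.
#'
#' @param pool a `HaplotypePool`.
#' @param pedigree a [Pedigree-class] (topologically sorted by
#'   construction).
#' @param markerPositions,qtlPositions locus positions (bp) present in the
#'   pool (QTL may be empty).
#' @param config a [simConfig()] list (uses map and physical lengths).
#' @param seed optional RNG seed.
#' @param returnHaplotypes if `TRUE`, also return the full 0/1 haplotype
#'   matrix (2 rows per individual) — intended for small pedigrees.
#' @return list with `genotypes` (a [GenotypeMatrix-class] of marker
#'   dosages for genotyped individuals), `qtlDosage` (matrix, all
#'   individuals x QTL), and optionally `haplotypes`.
#' @export
geneDrop <- function(pool, pedigree, markerPositions, qtlPositions = integer(),
                     config = pool$config, seed = NULL,
                     returnHaplotypes = FALSE) {
  loci <- sort(unique(c(markerPositions, qtlPositions)))
  missingLoci <- setdiff(loci, pool$positions)
  if (length(missingLoci))
    stop("locus position(s) absent from the pool: ",
         paste(utils::head(missingLoci, 3), collapse = ", "))
  poolMat <- vapply(pool$haplotypes, function(h)
    as.integer(loci %in% h), integer(length(loci)))
  poolMat <- t(poolMat) # 2Ne x L
  r <- pedRecords(pedigree)
  idx <- seq_len(nrow(r))
  names(idx) <- r$id
  sire <- ifelse(is.na(r$sire), 0L, idx[r$sire])
  dam <- ifelse(is.na(r$dam), 0L, idx[r$dam])
  genoRows <- which(r$genotyped)
  if (!length(genoRows)) stop("pedigree has no genotyped individuals")
  res <- withSeed(seed,
    gene_drop_cpp(poolMat, as.integer(sire), as.integer(dam),
                  as.numeric(loci), config$genomeLengthMorgan,
                  config$genomeLengthBp,
                  match(sort(markerPositions), loci),
                  match(sort(qtlPositions), loci),
                  as.integer(genoRows), returnHaplotypes))
  if (res$pool_exhausted)
    message("founder haplotype pool exhausted; continuing with replacement")
  md <- res$marker_dosage
  dimnames(md) <- list(r$id[genoRows], paste0("m", sort(markerPositions)))
  qd <- res$qtl_dosage
  dimnames(qd) <- list(r$id, if (length(qtlPositions))
    paste0("q", sort(qtlPositions)) else NULL)
  out <- list(genotypes = GenotypeMatrix(md), qtlDosage = qd)
  if (returnHaplotypes) {
    hm <- res$haplotypes
    rownames(hm) <- paste(rep(r$id, each = 2), c("a", "b"), sep = ".")
    colnames(hm) <- paste0("p", loci)
    out$haplotypes <- hm
  }
  out
}

#' Simulate a trait from QTL dosages
#'
#' QTL effects are Laplace(0, `laplaceScale`) draws; true breeding values
#' are the dosage-weighted effect sums.  The realized genetic variance is
#' the empirical variance of TBV among training individuals, and the
#' residual variance is set from the target per-chromosome heritability:
#' \eqn{\sigma_e^2 = V_g (1 - h^2_{chr})/h^2_{chr}}.  Phenotypes
#' \eqn{y = TBV + e} are generated for training individuals only
#' (evaluation individuals are genotype-only).
#'
#' @param qtlDosage matrix of QTL dosages, all pedigree individuals x QTL.
#' @param pedigree the [Pedigree-class] the dosages came from.
#' @param config a [simConfig()] list (uses `h2Chr`, `laplaceScale`).
#' @param seed optional RNG seed.
#' @return a `SimulatedTrait` list: `qtlEffects`, `trueBv` (all
#'   individuals), `phenotypes` (training only), `realizedVg`, `residVar`.
#' @export
makeTrait <- function(qtlDosage, pedigree, config, seed = NULL) {
  r <- pedRecords(pedigree)
  if (nrow(qtlDosage) != nrow(r))
    stop("qtlDosage must have one row per pedigree individual")
  training <- r$id[r$role == "training"]
  if (!length(training)) stop("pedigree has no training individuals")
  withSeed(seed, {
    a <- rlaplace(ncol(qtlDosage), config$laplaceScale)
    tbv <- setNames(drop(qtlDosage %*% a), r$id)
    vg <- var(tbv[training])
    if (!is.finite(vg) || vg <= 0)
      stop("degenerate trait: realized genetic variance is zero ",
           "(all QTL monomorphic among training individuals); re-simulate")
    ve <- vg * (1 - config$h2Chr) / config$h2Chr
    y <- tbv[training] + rnorm(length(training), 0, sqrt(ve))
    structure(list(qtlEffects = setNames(a, colnames(qtlDosage)),
                   trueBv = tbv, phenotypes = y, realizedVg = vg,
                   residVar = ve, h2Chr = config$h2Chr),
              class = "SimulatedTrait")
  })
}

#' @export
print.SimulatedTrait <- function(x, ...) {
  cat("SimulatedTrait:", length(x$qtlEffects), "QTL,",
      length(x$phenotypes), "phenotyped individuals\n")
  cat("  realized Vg =", signif(x$realizedVg, 5), ", sigma_e^2 =",
      signif(x$residVar, 5), "(h2_chr =", x$h2Chr, ")\n")
  invisible(x)
}

#' Simulate one complete dataset
#'
#' Convenience pipeline: (optionally) simulate the historical population,
#' sample disjoint marker/QTL sets, generate (or reuse) a pedigree,
#' gene-drop, and build the trait.  A pool and pedigree may be passed in so
#' that replicates share one history and pedigree while re-sampling loci,
#' transmissions and effects — the replication scheme of a fixed real
#' pedigree.
#'
#' @param config a [simConfig()] list.
#' @param seed RNG seed driving every stage (stage seeds are derived from
#'   it deterministically).
#' @param pool optional pre-simulated `HaplotypePool`.
#' @param pedigree optional [Pedigree-class]; defaults to
#'   [generatePedigree()] defaults.
#' @param ... passed to [generatePedigree()] when `pedigree` is `NULL`.
#' @return list with `genotypes` (all genotyped individuals), `trait`,
#'   `pedigree`, `loci`, `piNominal` (= nQtl/nMarkers), plus the training
#'   phenotypes and the ids of the training and evaluation sets.
#' @export
simulateDataset <- function(config = simConfig(), seed = NULL, pool = NULL,
                            pedigree = NULL, ...) {
  seeds <- deriveSeeds(if (is.null(seed)) sample.int(2^31 - 1, 1) else seed, 4)
  if (is.null(pool))
    pool <- simulateIdealPopulation(config, seed = seeds[1])
  if (is.null(pedigree))
    pedigree <- generatePedigree(..., seed = seeds[2])
  loci <- sampleLoci(pool, config, seed = seeds[3])
  withSeed(seeds[4], {
    drop <- geneDrop(pool, pedigree, loci$markerPositions,
                     loci$qtlPositions, config)
    trait <- makeTrait(drop$qtlDosage, pedigree, config)
    r <- pedRecords(pedigree)
    list(genotypes = drop$genotypes, trait = trait, pedigree = pedigree,
         loci = loci, piNominal = config$nQtl / config$nMarkers,
         phenotypes = trait$phenotypes,
         trainingIds = r$id[r$role == "training"],
         evaluationIds = r$id[r$role == "evaluation"])
  })
}

#' Write a simulated dataset to a directory
#'
#' Emits the standard file set: `genotypes.tsv`, `pedigree.tsv`,
#' `phenotypes.tsv`, `truth.tsv` (id, TBV) and `qtl.tsv` (position,
#' effect).
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  writePedigree(sim$pedigree, file.path(dir, "pedigree.tsv"))
  writePhenotypes(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
  write.table(data.frame(id = names(sim$trait$trueBv),
                         tbv = unname(sim$trait$trueBv)),
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(position = sim$loci$qtlPositions,
                         effect = unname(sim$trait$qtlEffects)),
              file.path(dir, "qtl.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
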