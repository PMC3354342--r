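test_that("the forward simulator is deterministic and respects zero mutation", {
  cfg <- simConfig(effectiveSize = 20, nGenerationsHistory = 50,
                   genomeLengthBp = 1e5, mutationRate = 1e-5)
  p1 <- simulateIdealPopulation(cfg, seed = 5)
  p2 <- simulateIdealPopulation(cfg, seed = 5)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$positions, p2$positions)
  p3 <- simulateIdealPopulation(cfg, seed = 6)
  expect_false(identical(p1$positions, p3$positions))
  # no mutation, monomorphic start: never any segregating site
  cfg0 <- simConfig(effectiveSize = 20, nGenerationsHistory = 50,
                    genomeLengthBp = 1e5, mutationRate = 0)
  p0 <- simulateIdealPopulation(cfg0, seed = 7)
  expect_length(p0$positions, 0)
  # frequencies are strictly polymorphic (fixed/lost pruned)
  expect_true(all(p1$freq > 0 & p1$freq < 1))
})

test_that("segregating sites at equilibrium match Watterson's prediction", {
  # theta = 4 Ne mu L = 20; expectation theta * sum_{k<2Ne} 1/k
  ne <- 50
  muL <- 0.1
  theta <- 4 * ne * muL
  cfg <- simConfig(effectiveSize = ne, nGenerationsHistory = 10 * ne,
                   genomeLengthBp = 1e7, mutationRate = muL / 1e7)
  S <- vapply(1:20, function(r)
    length(simulateIdealPopulation(cfg, seed = 1000 + r)$positions), 0L)
  expected <- theta * sum(1 / seq_len(2 * ne - 1))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("locus sampling enforces the MAF filter and disjointness", {
  cfg <- smallSimConfig()
  pool <- simulateIdealPopulation(cfg, seed = 21)
  loci <- sampleLoci(pool, cfg, seed = 22)
  expect_length(loci$markerPositions, cfg$nMarkers)
  expect_length(loci$qtlPositions, cfg$nQtl)
  expect_length(intersect(loci$markerPositions, loci$qtlPositions), 0)
  maf <- pmin(pool$freq, 1 - pool$freq)
  names(maf) <- pool$positions
  expect_true(all(maf[as.character(loci$markerPositions)] >= 0.05))
  expect_true(all(maf[as.character(loci$qtlPositions)] >= 0.05))
  # exhaustive boundary: take every qualifying site
  nOk <- sum(maf >= 0.05)
  cfgAll <- smallSimConfig(nMarkers = nOk - cfg$nQtl)
  lociAll <- sampleLoci(pool, cfgAll, seed = 23)
  expect_length(lociAll$markerPositions, nOk - cfg$nQtl)
  cfgTooMany <- smallSimConfig(nMarkers = nOk + 1)
  expect_error(sampleLoci(pool, cfgTooMany, seed = 24), "longer history")
})

test_that("the layered pedigree generator honours its contracts", {
  ped <- generatePedigree(nTotal = 200, nGenerations = 4, nGenotyped = 60,
                          nTraining = 40, nEvaluation = 10, seed = 31)
  r <- pedRecords(ped)
  expect_equal(nrow(r), 200)
  expect_true(validObject(ped))
  expect_equal(sum(r$genotyped), 60)
  expect_equal(sum(r$role == "training"), 40)
  expect_equal(sum(r$role == "evaluation"), 10)
  # training bulls are older (earlier) than evaluation bulls
  expect_lt(max(which(r$role == "training")),
            min(which(r$role == "evaluation")))
  # one generation: all founders
  ped1 <- generatePedigree(nTotal = 10, nGenerations = 1, nGenotyped = 10,
                           nTraining = 6, nEvaluation = 4, seed = 32)
  expect_true(all(is.na(pedRecords(ped1)$sire)))
  # determinism
  pedA <- generatePedigree(nTotal = 100, nGenerations = 3, nGenotyped = 30,
                           nTraining = 20, nEvaluation = 10, seed = 33)
  pedB <- generatePedigree(nTotal = 100, nGenerations = 3, nGenotyped = 30,
                           nTraining = 20, nEvaluation = 10, seed = 33)
  expect_identical(pedRecords(pedA), pedRecords(pedB))
  expect_error(generatePedigree(nTotal = 10, nGenotyped = 20,
                                nTraining = 5, nEvaluation = 5), "<=")
})

test_that("the default pedigree mirrors the emulated population counts", {
  ped <- generatePedigree(seed = 34)
  r <- pedRecords(ped)
  expect_equal(nrow(r), 19523)
  expect_equal(sum(r$genotyped), 2165)
  expect_equal(sum(r$role == "training"), 1915)
  expect_equal(sum(r$role == "evaluation"), 250)
  expect_true(validObject(ped))
})

test_that("gene-dropping is Mendelian-consistent and conserves alleles", {
  # hand-built pool over 4 positions; allele at position 400 absent
  pool <- handPool(
    haplotypes = list(c(100L), c(100L, 200L), c(200L, 300L), c(300L),
                      c(100L, 300L), integer(0)),
    positions = c(100L, 200L, 300L, 400L),
    config = simConfig())
  ped <- smallPedigree()
  suppressMessages(suppressWarnings(
    drop <- geneDrop(pool, ped, markerPositions = c(100, 200, 300, 400),
                     config = simConfig(), seed = 41,
                     returnHaplotypes = TRUE)))  # p400 may be monomorphic
  h <- drop$haplotypes
  d <- dosages(drop$genotypes)  # warning-free: retained markers only
  r <- pedRecords(ped)
  # Mendelian: each transmitted allele matches one parental allele per
  # segment; with whole haplotypes available, check offspring dosage lies
  # within the parental transmissible range at every locus
  for (i in which(!is.na(r$sire))) {
    for (loc in colnames(h)) {
      sirePair <- h[paste(r$sire[i], c("a", "b"), sep = "."), loc]
      damPair <- h[paste(r$dam[i], c("a", "b"), sep = "."), loc]
      off <- h[paste(r$id[i], c("a", "b"), sep = "."), loc]
      expect_true(off[1] %in% sirePair)
      expect_true(off[2] %in% damPair)
    }
  }
  # conservation: position 400 absent from every founder, so never appears
  expect_true(all(h[, "p400"] == 0))
})

test_that("zero map length transmits whole parental haplotypes", {
  pool <- handPool(
    haplotypes = list(c(10L, 30L), c(20L), c(10L, 20L, 30L), integer(0)),
    positions = c(10L, 20L, 30L))
  cfg <- simConfig(genomeLengthMorgan = 0)
  ped <- Pedigree(id = c("f1", "f2", "o1"), sire = c(NA, NA, "f1"),
                  dam = c(NA, NA, "f2"), genotyped = TRUE,
                  role = c("training", "training", "evaluation"))
  suppressMessages(
    drop <- geneDrop(pool, ped, markerPositions = c(10, 20, 30),
                     config = cfg, seed = 42, returnHaplotypes = TRUE))
  h <- drop$haplotypes
  expect_true(any(apply(h[c("f1.a", "f1.b"), ], 1, identical, h["o1.a", ])))
  expect_true(any(apply(h[c("f2.a", "f2.b"), ], 1, identical, h["o1.b", ])))
})

test_that("founder allele frequencies track the pool frequencies", {
  cfg <- smallSimConfig()
  pool <- simulateIdealPopulation(cfg, seed = 51)
  loci <- sampleLoci(pool, cfg, seed = 52)
  # all-founder pedigree, everyone genotyped: the drop just samples the pool
  n <- 30
  ped <- generatePedigree(nTotal = n, nGenerations = 1, nGenotyped = n,
                          nTraining = 20, nEvaluation = 10, seed = 53)
  poolFreq <- setNames(pool$freq, pool$positions)
  reps <- 20
  freqs <- matrix(0, reps, cfg$nMarkers)
  for (rseed in seq_len(reps)) {
    suppressMessages(
      drop <- geneDrop(pool, ped, loci$markerPositions, config = cfg,
                       seed = 500 + rseed))
    d <- drop$genotypes
    freqs[rseed, match(markerIds(d),
                       paste0("m", loci$markerPositions))] <-
      unname(alleleFreq(d))
  }
  fbar <- colMeans(freqs)
  p <- unname(poolFreq[as.character(loci$markerPositions)])
  se <- sqrt(p * (1 - p) / (2 * n * reps))
  expect_true(mean(abs(fbar - p) <= 3 * se) > 0.95)
})

test_that("trait construction follows the heritability identity", {
  qtl <- matrix(rbinom(200 * 10, 2, 0.4), 200, 10,
                dimnames = list(paste0("ind", 1:200), paste0("q", 1:10)))
  ped <- generatePedigree(nTotal = 200, nGenerations = 2, nGenotyped = 150,
                          nTraining = 100, nEvaluation = 50, seed = 61)
  qtl <- qtl[pedRecords(ped)$id, ]  # align rows
  cfg <- simConfig(h2Chr = 0.5)
  tr <- makeTrait(qtl, ped, cfg, seed = 62)
  expect_equal(tr$residVar, tr$realizedVg)  # h2 = 0.5
  expect_equal(length(tr$phenotypes), 100)
  expect_equal(tr$trueBv,
               setNames(drop(qtl %*% tr$qtlEffects), rownames(qtl)))
  # degenerate QTL: monomorphic dosages carry no variance
  qtl0 <- matrix(2, 200, 3, dimnames = list(pedRecords(ped)$id, NULL))
  expect_error(makeTrait(qtl0, ped, cfg, seed = 63), "degenerate")
})

test_that("phenotypic variance decomposes into genetic plus residual", {
  withr::local_seed(71)
  ratios <- vapply(1:20, function(r) {
    qtl <- matrix(rbinom(600 * 20, 2, runif(1, 0.2, 0.8)), 600, 20)
    rownames(qtl) <- paste0("ind", 1:600)
    ped <- generatePedigree(nTotal = 600, nGenerations = 1,
                            nGenotyped = 600, nTraining = 550,
                            nEvaluation = 50, seed = 700 + r)
    tr <- makeTrait(qtl[pedRecords(ped)$id, ], ped, simConfig(h2Chr = 0.3),
                    seed = 800 + r)
    var(tr$phenotypes) / (tr$realizedVg + tr$residVar)
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 3 * sd(ratios) / sqrt(length(ratios)))
})

test_that("the full synthetic pipeline is reproducible bit-exact", {
  cfg <- smallSimConfig()
  ped <- generatePedigree(nTotal = 120, nGenerations = 3, nGenotyped = 60,
                          nTraining = 45, nEvaluation = 15, seed = 81)
  s1 <- simulateDataset(cfg, seed = 82, pedigree = ped)
  s2 <- simulateDataset(cfg, seed = 82, pedigree = ped)
  expect_identical(dosages(s1$genotypes), dosages(s2$genotypes))
  expect_identical(s1$trait$qtlEffects, s2$trait$qtlEffects)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$loci, s2$loci)
})

test_that("datasets round-trip through the on-disk file set", {
  cfg <- smallSimConfig()
  ped <- generatePedigree(nTotal = 80, nGenerations = 2, nGenotyped = 40,
                          nTraining = 30, nEvaluation = 10, seed = 91)
  sim <- simulateDataset(cfg, seed = 92, pedigree = ped)
  dir <- withr::local_tempdir()
  writeDataset(sim, dir)
  g <- readGenotypes(file.path(dir, "genotypes.tsv"))
  expect_identical(dosages(g), dosages(sim$genotypes))
  y <- readPhenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(y, sim$phenotypes)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), nrow(pedRecords(sim$pedigree)))
})
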