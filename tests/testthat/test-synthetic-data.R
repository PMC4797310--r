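test_that("simulated genomes are deterministic with per-chromosome 0-based ranks", {
  feats <- emptyFeatures()
  cfg <- simulationConfig(seed = 2, nChromosomes = 2L, genesPerChromosome = 100L,
                          plantedClusters = feats$clusters,
                          plantedMarkRuns = feats$runs,
                          tandemArrays = feats$arrays)
  lay <- simulateGenome(cfg)
  expect_equal(nGenes(lay), 200L)
  expect_equal(anyDuplicated(geneIds(lay)), 0L)
  r <- geneRanks(lay)
  expect_equal(unname(range(r)), c(0L, 99L))
  expect_identical(simulateGenome(cfg)@genes, lay@genes)
  expect_error(simulationConfig(genesPerChromosome = 0,
                                plantedClusters = feats$clusters,
                                plantedMarkRuns = feats$runs,
                                tandemArrays = feats$arrays))
})

test_that("planted expression blocks carry the target correlation; background stays near zero", {
  feats <- emptyFeatures()
  base <- list(seed = 13, nChromosomes = 1L, genesPerChromosome = 60L,
               nSamples = 500L, plantedMarkRuns = feats$runs,
               tandemArrays = feats$arrays)

  # rho = 1: the shared factor alone, within-block PCC exactly 1
  cfg1 <- do.call(simulationConfig, c(base, list(
    plantedClusters = data.frame(chrom = 1L, start_rank = 10L, width = 4L, rho = 1))))
  lay <- simulateGenome(cfg1)
  ex1 <- simulateExpression(cfg1, lay)
  blk <- mgcMiner:::featureGenes(cfg1, 1L, 10L, 4L)
  cc <- cor(t(ex1[blk, ]))
  expect_equal(unname(cc[upper.tri(cc)]), rep(1, 6))

  # rho = 0.8 at 500 samples: mean within-block PCC within 0.05
  cfg8 <- do.call(simulationConfig, c(base, list(
    plantedClusters = data.frame(chrom = 1L, start_rank = 10L, width = 5L, rho = 0.8))))
  ex8 <- simulateExpression(cfg8, simulateGenome(cfg8))
  blk8 <- mgcMiner:::featureGenes(cfg8, 1L, 10L, 5L)
  cc8 <- cor(t(ex8[blk8, ]))
  expect_lt(abs(mean(cc8[upper.tri(cc8)]) - 0.8), 0.05)

  # background pairs stay near zero correlation
  bg <- cor(ex8["chr1_g0050", ], ex8["chr1_g0055", ])
  expect_lt(abs(bg), 0.15)
  expect_error(do.call(simulationConfig, c(base, list(
    plantedClusters = data.frame(chrom = 1L, start_rank = 1L, width = 3L, rho = 1.2)))),
    "rho")
})

test_that("mark simulation honours the background rate and planted runs", {
  feats <- emptyFeatures()
  mk <- function(p, runs) {
    cfg <- simulationConfig(seed = 4, nChromosomes = 1L,
                            genesPerChromosome = 50L,
                            plantedClusters = feats$clusters,
                            plantedMarkRuns = runs,
                            tandemArrays = feats$arrays,
                            backgroundMarkRate = p)
    simulateMarks(cfg, simulateGenome(cfg))
  }
  run5 <- data.frame(chrom = 1L, start_rank = 10L, length = 5L)
  expect_equal(nMarked(mk(0, run5)), 5L)
  expect_equal(nMarked(mk(1, feats$runs)), 50L)

  # binomial bound at the genome-wide rate
  cfgBig <- simulationConfig(seed = 4, nChromosomes = 1L,
                             genesPerChromosome = 27206L,
                             plantedClusters = feats$clusters,
                             plantedMarkRuns = feats$runs,
                             tandemArrays = feats$arrays,
                             backgroundMarkRate = 0.17)
  kBig <- nMarked(simulateMarks(cfgBig, simulateGenome(cfgBig)))
  expect_lt(abs(kBig - 0.17 * 27206), 4 * sqrt(27206 * 0.17 * 0.83))
})

test_that("tandem-array families yield complete strict pairs nested in loose pairs", {
  feats <- emptyFeatures()
  mkDup <- function(width, fams, extra = 0L) {
    cfg <- simulationConfig(seed = 6, nChromosomes = 1L,
                            genesPerChromosome = 40L,
                            plantedClusters = feats$clusters,
                            plantedMarkRuns = feats$runs,
                            tandemArrays = data.frame(
                              chrom = 1L, start_rank = 5L, width = width,
                              n_families = fams, rho = 0.9),
                            extraLoosePairs = extra)
    simulateDuplicates(cfg, simulateGenome(cfg))
  }
  d <- mkDup(6L, 2L)
  expect_equal(nrow(d$strict@pairs), 6L)  # 2 families of 3: 2 * C(3,2)
  expect_equal(nrow(d$loose@pairs), 6L)
  none <- mkDup(4L, 4L)                    # one family per gene: no pairs
  expect_equal(nrow(none$strict@pairs), 0L)

  withExtra <- mkDup(6L, 2L, extra = 10L)
  sk <- mgcMiner:::pairKey(withExtra$strict@pairs[, 1], withExtra$strict@pairs[, 2])
  lk <- mgcMiner:::pairKey(withExtra$loose@pairs[, 1], withExtra$loose@pairs[, 2])
  expect_true(all(sk %in% lk))
  expect_gt(length(lk), length(sk))
})

test_that("every generated object feeds its pipeline stage without conversion", {
  cfg <- simulationConfig(seed = 44, nChromosomes = 1L, genesPerChromosome = 300L,
                          nSamples = 80L,
                          plantedClusters = data.frame(
                            chrom = 1L, start_rank = c(30L, 120L, 210L),
                            width = 5L, rho = 0.9),
                          plantedMarkRuns = data.frame(
                            chrom = 1L, start_rank = c(30L, 120L, 210L),
                            length = 5L),
                          tandemArrays = emptyFeatures()$arrays)
  lay <- simulateGenome(cfg)
  expr <- simulateExpression(cfg, lay)
  track <- simulateMarks(cfg, lay)
  dups <- simulateDuplicates(cfg, lay)
  rpkm <- simulateRpkm(cfg, lay)
  graph <- buildGeneGraph(bandedPCC(expr, lay, 10), 0.65, dups$loose)
  final <- filterTandemArrays(
    intersectClusters(cliqueClusters(graph, lay), track, lay),
    dups$strict)
  expect_setequal(memberKeys(final), memberKeys(plantedTruth(cfg, lay)))
  regions <- findMisregulatedRegions(foldChanges(rpkm), lay)
  expect_gte(nClusters(regions), 3L)
})
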