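test_that("fold changes use the pseudocount-guarded log2 ratio", {
  m <- rbind(g1 = c(10, 43, 10, 10, 10),
             g2 = c(0, 0, 0, 0, 0),
             g3 = c(100, 100, 100, 100, 100))
  colnames(m) <- c("Col0", "m1", "m2", "m3", "m4")
  tab <- RpkmTable(m, "Col0")
  fc <- foldChanges(tab, epsilon = 1)
  expect_equal(fc["g1", "m1"], log2(44 / 11))  # exactly 2
  expect_equal(fc["g1", "m1"], 2.0)
  expect_equal(fc["g2", "m1"], 0.0)            # 0 vs 0 guarded by epsilon
  expect_equal(fc["g3", "m2"], 0.0)
  expect_equal(dim(fc), c(3L, 4L))
  expect_error(RpkmTable(m * -1, "Col0"), "non-negative")
})

test_that("regions require >= minGenes contiguous qualifying genes in one direction", {
  ids <- sprintf("g%02d", 1:8)
  lay <- tinyLayout(ids)
  mkFc <- function(downGenes, value = -2) {
    fc <- matrix(0, 8, 4, dimnames = list(ids, paste0("m", 1:4)))
    fc[downGenes, 1:3] <- value   # change in 3 of 4 mutants
    fc
  }
  # 3 adjacent genes >= 2-fold down in 3 of 4 mutants: one down region
  one <- findMisregulatedRegions(mkFc(2:4), lay)
  expect_equal(nClusters(one), 1L)
  expect_identical(clusterTable(one)$direction, "down")
  expect_identical(clusterMembers(one)[[1]], ids[2:4])

  # middle gene only 1.5-fold changed: no region
  fcWeak <- mkFc(2:4); fcWeak["g03", ] <- c(-log2(1.5), -log2(1.5), -log2(1.5), 0)
  expect_equal(nClusters(findMisregulatedRegions(fcWeak, lay)), 0L)

  # 2 qualifying, 1 non-qualifying, 2 qualifying: no stretch of 3
  expect_equal(nClusters(findMisregulatedRegions(mkFc(c(2, 3, 5, 6)), lay)), 0L)

  # change in only 2 of 4 mutants does not qualify
  fc2 <- matrix(0, 8, 4, dimnames = list(ids, paste0("m", 1:4)))
  fc2[2:4, 1:2] <- -2
  expect_equal(nClusters(findMisregulatedRegions(fc2, lay)), 0L)

  # opposite directions do not merge into one region by default,
  # but mixed qualification is allowed when relaxed
  fcMix <- mkFc(2:3); fcMix["g04", 1:3] <- 2
  expect_equal(nClusters(findMisregulatedRegions(fcMix, lay)), 0L)
  relaxed <- findMisregulatedRegions(fcMix, lay, sharedDirection = FALSE)
  expect_equal(nClusters(relaxed), 1L)
  expect_identical(clusterTable(relaxed)$direction, "mixed")
})

test_that("raising thresholds shrinks region coverage and nests regions in looser calls", {
  set.seed(33)
  ids <- sprintf("g%03d", 1:120)
  lay <- tinyLayout(ids)
  fc <- matrix(rnorm(120 * 4, 0, 1.2), 120, 4,
               dimnames = list(ids, paste0("m", 1:4)))
  fc[20:26, 1:3] <- fc[20:26, 1:3] - 3
  nested <- function(strictSet, looseSet) {
    looseMembers <- clusterMembers(looseSet)
    for (s in clusterMembers(strictSet))
      expect_true(any(vapply(looseMembers, function(m) all(s %in% m),
                             logical(1))))
  }
  prev <- NULL
  for (minAbs in c(0.5, 1, 1.5)) {
    cur <- findMisregulatedRegions(fc, lay, minAbsLog2fc = minAbs, minMutants = 3)
    if (!is.null(prev)) {
      # covered genes never grow, and every stricter region sits inside a looser one
      expect_lte(sum(clusterTable(cur)$n_members),
                 sum(clusterTable(prev)$n_members))
      nested(cur, prev)
    }
    prev <- cur
  }
  strict <- findMisregulatedRegions(fc, lay, minMutants = 4)
  loose <- findMisregulatedRegions(fc, lay, minMutants = 3)
  expect_lte(sum(clusterTable(strict)$n_members),
             sum(clusterTable(loose)$n_members))
  nested(strict, loose)
})

test_that("planted down-regulated clusters are recovered from simulated RPKM", {
  cfg <- simulationConfig(seed = 29)
  lay <- simulateGenome(cfg)
  rpkm <- simulateRpkm(cfg, lay)
  fc <- foldChanges(rpkm)
  regions <- findMisregulatedRegions(fc, lay)
  truth <- memberKeys(plantedTruth(cfg, lay))
  found <- memberKeys(regions)
  # every planted cluster is recovered as (or within) a reported region
  for (t in truth) {
    tGenes <- strsplit(t, ";")[[1]]
    expect_true(any(vapply(found, function(f)
      all(tGenes %in% strsplit(f, ";")[[1]]), logical(1))))
  }
  # false-positive regions involve fewer than 1% of background genes
  bgGenes <- setdiff(unlist(clusterMembers(regions)),
                     unlist(strsplit(truth, ";")))
  expect_lt(length(bgGenes) / nGenes(lay), 0.01)
})

test_that("noise-free simulated mutants reproduce the planted effect exactly on the raw ratio", {
  cfg <- simulationConfig(seed = 3, noiseSd = 0)
  lay <- simulateGenome(cfg)
  rpkm <- simulateRpkm(cfg, lay)
  g <- mgcMiner:::featureGenes(cfg, cfg@plantedClusters$chrom[1],
                               cfg@plantedClusters$start_rank[1],
                               cfg@plantedClusters$width[1])
  v <- rpkm@values
  expect_equal(unname(log2(v[g, "arp6"] / v[g, "Col0"])), rep(-2, 5))
  expect_equal(unname(log2(v[g, "hta9_hta11"] / v[g, "Col0"])), rep(0, 5))
})
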