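test_that("probe collapse keeps the largest-IQR probe per gene, ties by probe ID", {
  m <- rbind(p1 = c(1, 2, 3, 10), p2 = c(5, 5.5, 6, 6.5),
             p3 = c(0, 0, 0, 0), p4 = c(2, 4, 6, 8))
  map <- c(p1 = "gX", p2 = "gX", p4 = "gY")
  out <- collapseProbes(m, map)
  expect_identical(rownames(out), c("gX", "gY"))
  expect_equal(unname(out["gX", ]), unname(m["p1", ]))  # larger IQR wins
  expect_equal(unname(out["gY", ]), unname(m["p4", ]))  # single probe kept

  # equal IQR via a constant shift: lexicographically smaller probe wins
  m2 <- rbind(pB = c(1, 2, 3, 4), pA = c(11, 12, 13, 14))
  out2 <- collapseProbes(m2, c(pA = "g1", pB = "g1"))
  expect_equal(unname(out2["g1", ]), unname(m2["pA", ]))

  expect_error(collapseProbes(m, character(0)), "empty")
  expect_error(collapseProbes(m, c(p1 = "gX", p1 = "gY")),
               "more than one gene")
})

test_that("banded PCC hits exact values and respects the band boundary", {
  lay <- tinyLayout(c("a", "b", "c", "d"))
  expr <- rbind(a = c(1, 2, 3, 4, 5),
                b = c(2, 4, 6, 8, 10),      # identical profile shape
                c = c(5, 4, 3, 2, 1),       # negation
                d = c(1, 1, 2, 1, 3))
  pcc <- bandedPCC(expr, lay, g = 2)
  key <- paste(pcc$gene_a, pcc$gene_b)
  expect_equal(pcc$pcc[key == "a b"], 1.0)
  expect_equal(pcc$pcc[key == "a c"], -1.0)
  expect_false("a d" %in% key)  # distance 3 > g = 2
  pcc3 <- bandedPCC(expr, lay, g = 3)
  expect_true("a d" %in% paste(pcc3$gene_a, pcc3$gene_b))
})

test_that("zero-variance rows are excluded from the correlation map", {
  lay <- tinyLayout(c("a", "b", "c"))
  expr <- rbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(3, 1, 2))
  expect_message(pcc <- bandedPCC(expr, lay, g = 2), "zero-variance")
  expect_false("b" %in% c(pcc$gene_a, pcc$gene_b))
  expect_false("b" %in% attr(pcc, "universe"))
})

test_that("banded PCC agrees with dense correlation restricted to the band", {
  set.seed(71)
  n <- 120
  ids <- sprintf("g%03d", seq_len(n))
  lay <- tinyLayout(ids, chrom = rep(c("chr1", "chr2"), each = 60))
  expr <- matrix(rnorm(n * 20), n, 20, dimnames = list(ids, NULL))
  g <- 7
  pcc <- bandedPCC(expr, lay, g)
  dense <- cor(t(expr))
  for (i in seq_len(nrow(pcc)))
    expect_equal(pcc$pcc[i], dense[pcc$gene_a[i], pcc$gene_b[i]],
                 tolerance = 1e-10)
  # and the band contains exactly the same-chromosome pairs within g
  expected <- sum(vapply(c(60, 60), function(m)
    sum(pmin(g, m - seq_len(m - 1))), numeric(1)))
  expect_equal(nrow(pcc), expected)
})

test_that("edge rule is PCC >= c with duplicate pairs removed", {
  lay <- tinyLayout(c("a", "b", "c"))
  pcc <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                    distance = 1L, pcc = c(0.65, 0.9))
  attr(pcc, "universe") <- c("a", "b", "c"); attr(pcc, "g") <- 1L
  g1 <- buildGeneGraph(pcc, c = 0.65)
  expect_equal(igraph::ecount(g1@graph), 2L)  # 0.65 >= 0.65 inclusive
  dup <- DuplicatePairs(cbind("c", "b"), "loose")
  g2 <- buildGeneGraph(pcc, c = 0.65, dup)
  expect_equal(igraph::ecount(g2@graph), 1L)  # high-PCC duplicate removed
  empty <- pcc[0, ]
  attr(empty, "universe") <- c("a", "b", "c"); attr(empty, "g") <- 1L
  expect_equal(igraph::ecount(buildGeneGraph(empty, 0.5)@graph), 0L)
})

test_that("raising c never adds edges; raising g never removes them; duplicate removal is idempotent", {
  set.seed(5)
  ids <- sprintf("g%02d", 1:40)
  lay <- tinyLayout(ids)
  expr <- matrix(rnorm(40 * 12), 40, 12, dimnames = list(ids, NULL))
  dup <- DuplicatePairs(cbind("g01", "g02"), "loose")
  pccBig <- bandedPCC(expr, lay, g = 8)
  edgeSet <- function(g, c) {
    sub <- pccBig[pccBig$distance <= g, ]
    attr(sub, "universe") <- attr(pccBig, "universe"); attr(sub, "g") <- g
    gr <- buildGeneGraph(sub, c, dup)
    apply(igraph::as_edgelist(gr@graph), 1, function(r)
      paste(sort(r), collapse = "|"))
  }
  for (cs in list(c(0.1, 0.3), c(0.3, 0.6))) {
    expect_true(all(edgeSet(5, cs[2]) %in% edgeSet(5, cs[1])))
  }
  expect_true(all(edgeSet(4, 0.2) %in% edgeSet(8, 0.2)))
  # idempotence: pairs already removed stay removed
  once <- edgeSet(5, 0.2)
  expect_false("g01|g02" %in% once)
  expect_identical(sort(once), sort(edgeSet(5, 0.2)))
})

test_that("ACC matches hand counts and brute force, and stays in [0, 1]", {
  tri <- tinyGraph(c("a", "b", "c"), cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(averageClusteringCoefficient(tri), 1.0)
  path <- tinyGraph(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")))
  expect_equal(averageClusteringCoefficient(path), 0.0)
  # 4-cycle with one chord: local ccs 2/3, 1, 2/3, 1 -> mean 5/6
  chord <- tinyGraph(c("a", "b", "c", "d"),
                     cbind(c("a", "b", "c", "d", "a"),
                           c("b", "c", "d", "a", "c")))
  expect_equal(averageClusteringCoefficient(chord), 5 / 6)
  expect_equal(bruteACC(chord), 5 / 6)

  set.seed(31)
  for (i in 1:20) {
    g <- igraph::sample_gnp(12, runif(1, 0.1, 0.5))
    igraph::V(g)$name <- sprintf("n%02d", 1:12)
    gg <- methods::new("GeneGraph", graph = g, g = 11L, c = 0.5)
    acc <- averageClusteringCoefficient(gg)
    expect_gte(acc, 0); expect_lte(acc, 1)
    expect_equal(acc, bruteACC(gg), tolerance = 1e-12)
    accAll <- averageClusteringCoefficient(gg, allNodes = TRUE)
    expect_equal(accAll, bruteACC(gg, allNodes = TRUE), tolerance = 1e-12)
  }
  # edgeless graph scores 0
  lone <- tinyGraph(c("a", "b"), matrix(character(0), ncol = 2))
  expect_equal(averageClusteringCoefficient(lone), 0)
})

test_that("parameter search recovers the planted regime and breaks ties deterministically", {
  cfg <- simulationConfig(
    seed = 9, nChromosomes = 1L, genesPerChromosome = 200L, nSamples = 200L,
    plantedClusters = data.frame(chrom = 1L, start_rank = c(20L, 70L, 120L, 170L),
                                 width = 5L, rho = 0.9),
    plantedMarkRuns = emptyFeatures()$runs,
    tandemArrays = emptyFeatures()$arrays)
  lay <- simulateGenome(cfg)
  expr <- simulateExpression(cfg, lay)
  opt <- optimizeParameters(expr, lay, gGrid = 1:10,
                            cGrid = seq(0.3, 0.9, by = 0.1))
  expect_gte(opt$g, 4); expect_lte(opt$g, 10)
  # cutoff sits above the background correlation scale (~2/sqrt(n) here)
  expect_gt(opt$c, 0.3)
  expect_equal(dim(opt$surface), c(10L, 7L))
  expect_equal(opt$acc, max(opt$surface))

  # single grid point returns that point
  one <- optimizeParameters(expr, lay, gGrid = 5L, cGrid = 0.65)
  expect_equal(one$g, 5L); expect_equal(one$c, 0.65)

  # all-zero surface: warning plus smallest-g / largest-c tie-break
  noise <- matrix(rnorm(200 * 10), 200, 10, dimnames = list(geneIds(lay), NULL))
  expect_warning(
    flat <- optimizeParameters(noise, lay, gGrid = c(2L, 4L), cGrid = c(0.99, 1)),
    "identically zero")
  expect_equal(flat$g, 2L); expect_equal(flat$c, 1)
})
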