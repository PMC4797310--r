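# Synthetic study generator: genomes with planted co-expressed blocks,
# planted contiguous mark runs, tandem-array duplicate families, and mutant
# genotypes with coordinate down-regulation of planted clusters. Every
# generator is deterministic under the config seed and emits objects the
# corresponding pipeline stage consumes directly.

#' Build a SimulationConfig
#'
#' Defaults describe the desk-scale validation genome: 2 chromosomes of
#' 1,000 genes, 200 expression samples, 20 planted 5-gene clusters with
#' within-cluster correlation 0.9 (each under a matching 5-gene mark run,
#' members mutually unrelated so they count as >= 3 gene families), one
#' decoy tandem array per chromosome (6 co-expressed, fully marked genes
#' from only 2 duplicate families), one decoy mark-only run per chromosome,
#' a background mark rate of 0.17 (the genome-wide H3K27me3 fraction,
#' 4,629/27,206), and a log2 effect of -2 in 3 of the 4 H2A.Z-pathway
#' mutant genotypes for every planted cluster.
#'
#' @param seed master seed (all generators derive their streams from it).
#' @param nChromosomes,genesPerChromosome,nSamples genome and compendium size.
#' @param plantedClusters data.frame(chrom, start_rank, width, rho); NULL for
#'   the default 20-cluster layout.
#' @param plantedMarkRuns data.frame(chrom, start_rank, length); NULL covers
#'   every planted cluster and array plus one decoy run per chromosome.
#' @param tandemArrays data.frame(chrom, start_rank, width, n_families, rho);
#'   NULL for one decoy 2-family array per chromosome.
#' @param backgroundMarkRate independent per-gene mark probability.
#' @param mutants,wildType genotype names.
#' @param mutantEffects planted-clusters x mutants log2 effect matrix; NULL
#'   applies \code{defaultEffect} to the first three mutants.
#' @param defaultEffect log2 effect used when \code{mutantEffects} is NULL.
#' @param noiseSd sd of the log2 multiplicative noise on mutant RPKM.
#' @param rpkmMeanlog,rpkmSdlog log-normal parameters of wild-type RPKM.
#' @param extraLoosePairs additional random loose-only duplicate pairs.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             nChromosomes = 2L, genesPerChromosome = 1000L,
                             nSamples = 200L,
                             plantedClusters = NULL, plantedMarkRuns = NULL,
                             tandemArrays = NULL, backgroundMarkRate = 0.17,
                             mutants = c("arp6", "pie1", "swc6", "hta9_hta11"),
                             wildType = "Col0", mutantEffects = NULL,
                             defaultEffect = -2, noiseSd = 0.25,
                             rpkmMeanlog = log(100), rpkmSdlog = 0.75,
                             extraLoosePairs = 0L) {
  nChromosomes <- as.integer(nChromosomes)
  genesPerChromosome <- as.integer(genesPerChromosome)
  if (is.null(plantedClusters)) {
    perChrom <- 10L
    plantedClusters <- data.frame(
      chrom = rep(seq_len(nChromosomes), each = perChrom),
      start_rank = rep(40L + (seq_len(perChrom) - 1L) * 90L, nChromosomes),
      width = 5L, rho = 0.9)
  }
  if (is.null(tandemArrays)) {
    tandemArrays <- data.frame(
      chrom = seq_len(nChromosomes), start_rank = 940L,
      width = 6L, n_families = 2L, rho = 0.9)
  }
  if (is.null(plantedMarkRuns)) {
    plantedMarkRuns <- rbind(
      data.frame(chrom = plantedClusters$chrom,
                 start_rank = plantedClusters$start_rank,
                 length = plantedClusters$width),
      data.frame(chrom = tandemArrays$chrom,
                 start_rank = tandemArrays$start_rank,
                 length = tandemArrays$width),
      # decoy runs: marked but neither co-expressed nor duplicated
      data.frame(chrom = seq_len(nChromosomes), start_rank = 915L,
                 length = 5L))
  }
  if (is.null(mutantEffects)) {
    mutantEffects <- matrix(0, nrow(plantedClusters), length(mutants),
                            dimnames = list(NULL, mutants))
    if (length(mutants) >= 3L) mutantEffects[, 1:3] <- defaultEffect
    else mutantEffects[] <- defaultEffect
  }
  methods::new("SimulationConfig",
               nChromosomes = nChromosomes,
               genesPerChromosome = genesPerChromosome,
               nSamples = as.integer(nSamples),
               plantedClusters = plantedClusters,
               plantedMarkRuns = plantedMarkRuns,
               tandemArrays = tandemArrays,
               backgroundMarkRate = backgroundMarkRate,
               mutants = mutants, wildType = wildType,
               mutantEffects = mutantEffects, noiseSd = noiseSd,
               rpkmMeanlog = rpkmMeanlog, rpkmSdlog = rpkmSdlog,
               extraLoosePairs = as.integer(extraLoosePairs),
               seed = as.integer(seed))
}

#' @describeIn simulationConfig show a summary.
#' @param object a \code{SimulationConfig}.
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d chromosome(s) x %d genes, %d samples, seed %d\n",
    "  planted clusters: %d; tandem arrays: %d; planted mark runs: %d; ",
    "background mark rate %.2f\n"),
    object@nChromosomes, object@genesPerChromosome, object@nSamples,
    object@seed, nrow(object@plantedClusters), nrow(object@tandemArrays),
    nrow(object@plantedMarkRuns), object@backgroundMarkRate))
})

# Internal: chromosome name and gene IDs.
simChromName <- function(i) sprintf("chr%d", i)
simGeneIds <- function(chrom, m) sprintf("%s_g%04d", chrom, seq_len(m) - 1L)

#' Simulate the genome layout
#'
#' Evenly spaced, non-overlapping gene models (1 kb genes, 1 kb intergenic),
#' deterministic given the config.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{GenomeLayout}.
#' @export
simulateGenome <- function(config) {
  m <- config@genesPerChromosome
  genes <- do.call(rbind, lapply(seq_len(config@nChromosomes), function(i) {
    ch <- simChromName(i)
    start <- (seq_len(m) - 1L) * 2000L + 1L
    data.frame(chrom = ch, gene_id = simGeneIds(ch, m),
               start = start, end = start + 999L, strand = "+",
               stringsAsFactors = FALSE)
  }))
  GenomeLayout(genes, chromOrder = simChromName(seq_len(config@nChromosomes)))
}

# Internal: member gene IDs of a planted feature row.
featureGenes <- function(config, chrom, start, len) {
  ch <- simChromName(chrom)
  simGeneIds(ch, config@genesPerChromosome)[start + seq_len(len)]
}

#' Simulate the log2 expression compendium
#'
#' Each planted cluster (and each tandem array, which co-expresses like a
#' real duplicated block) shares a latent factor: member gene j in sample s
#' takes \eqn{\sqrt{\rho} z_s + \sqrt{1-\rho}\,\epsilon_{js}} with z and
#' \eqn{\epsilon} standard normal, so the expected within-block pairwise
#' correlation is exactly \eqn{\rho}. Background genes are iid normal. A
#' constant baseline of 8 puts values on a typical log2 microarray scale.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param layout layout from \code{\link{simulateGenome}}.
#' @return log2 expression matrix, genes x samples.
#' @export
simulateExpression <- function(config, layout) {
  n <- nGenes(layout); ns <- config@nSamples
  ids <- geneIds(layout)
  blocks <- rbind(
    config@plantedClusters[, c("chrom", "start_rank", "width", "rho")],
    config@tandemArrays[, c("chrom", "start_rank", "width", "rho")])
  withSeed(config@seed + 1L, {
    m <- matrix(stats::rnorm(n * ns), n, ns,
                dimnames = list(ids, sprintf("S%04d", seq_len(ns))))
    for (b in seq_len(nrow(blocks))) {
      rho <- blocks$rho[b]
      if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
      g <- featureGenes(config, blocks$chrom[b], blocks$start_rank[b],
                        blocks$width[b])
      z <- stats::rnorm(ns)
      eps <- matrix(stats::rnorm(length(g) * ns), length(g), ns)
      m[g, ] <- sqrt(rho) * rep(z, each = length(g)) + sqrt(1 - rho) * eps
    }
    m + 8
  })
}

#' Simulate the binary chromatin-mark track
#'
#' Background genes are marked independently at
#' \code{backgroundMarkRate}; planted runs are set fully marked.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param layout layout from \code{\link{simulateGenome}}.
#' @return a \linkS4class{MarkTrack}.
#' @export
simulateMarks <- function(config, layout) {
  ids <- geneIds(layout)
  marked <- withSeed(config@seed + 2L,
                     stats::runif(length(ids)) < config@backgroundMarkRate)
  names(marked) <- ids
  pr <- config@plantedMarkRuns
  for (b in seq_len(nrow(pr)))
    marked[featureGenes(config, pr$chrom[b], pr$start_rank[b], pr$length[b])] <- TRUE
  MarkTrack(names(marked)[marked], layout)
}

#' Simulate duplicate-pair tiers
#'
#' Within each tandem array, genes are partitioned round-robin into
#' \code{n_families}; all within-family pairs are emitted at the strict tier
#' (and therefore also at the loose tier). \code{extraLoosePairs} additional
#' random non-self pairs are emitted at the loose tier only.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param layout layout from \code{\link{simulateGenome}}.
#' @return list(loose =, strict =) of \linkS4class{DuplicatePairs}.
#' @export
simulateDuplicates <- function(config, layout) {
  ta <- config@tandemArrays
  pairs <- list()
  for (b in seq_len(nrow(ta))) {
    g <- featureGenes(config, ta$chrom[b], ta$start_rank[b], ta$width[b])
    fam <- split(g, rep_len(seq_len(ta$n_families[b]), length(g)))
    for (f in fam) if (length(f) >= 2L)
      pairs[[length(pairs) + 1L]] <- t(utils::combn(f, 2L))
  }
  strictPairs <- if (length(pairs)) do.call(rbind, pairs)
                 else matrix(character(0), ncol = 2)
  loosePairs <- strictPairs
  if (config@extraLoosePairs > 0L) {
    ids <- geneIds(layout)
    extra <- withSeed(config@seed + 3L, {
      a <- sample(ids, config@extraLoosePairs, replace = TRUE)
      b <- sample(ids, config@extraLoosePairs, replace = TRUE)
      cbind(a, b)[a != b, , drop = FALSE]
    })
    loosePairs <- rbind(loosePairs, extra)
  }
  list(loose = DuplicatePairs(loosePairs, "loose"),
       strict = DuplicatePairs(strictPairs, "strict"))
}

#' Simulate the wild-type / mutant RPKM table
#'
#' Wild-type RPKM is log-normal; each mutant value is the wild-type value
#' times \code{2^(effect + noise)} with \code{noise ~ N(0, noiseSd)} in log2
#' units. Effects apply only to planted-cluster genes in the genotypes named
#' by \code{mutantEffects}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param layout layout from \code{\link{simulateGenome}}.
#' @return an \linkS4class{RpkmTable}.
#' @export
simulateRpkm <- function(config, layout) {
  ids <- geneIds(layout)
  n <- length(ids)
  pc <- config@plantedClusters
  effect <- matrix(0, n, length(config@mutants),
                   dimnames = list(ids, config@mutants))
  for (b in seq_len(nrow(pc))) {
    g <- featureGenes(config, pc$chrom[b], pc$start_rank[b], pc$width[b])
    effect[g, ] <- matrix(config@mutantEffects[b, ], length(g),
                          length(config@mutants), byrow = TRUE)
  }
  withSeed(config@seed + 4L, {
    wt <- stats::rlnorm(n, config@rpkmMeanlog, config@rpkmSdlog)
    vals <- vapply(config@mutants, function(mu)
      wt * 2^(effect[, mu] + stats::rnorm(n, 0, config@noiseSd)),
      numeric(n))
    m <- cbind(wt, vals)
    colnames(m) <- c(config@wildType, config@mutants)
    rownames(m) <- ids
    RpkmTable(m, config@wildType)
  })
}

#' Planted ground truth as a cluster table
#'
#' The planted clusters of a config, as a \linkS4class{GeneClusterSet}
#' (provenance \code{"intersected"}) for comparison with pipeline output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param layout layout from \code{\link{simulateGenome}}.
#' @return a \linkS4class{GeneClusterSet}.
#' @export
plantedTruth <- function(config, layout) {
  pc <- config@plantedClusters
  sets <- lapply(seq_len(nrow(pc)), function(b)
    featureGenes(config, pc$chrom[b], pc$start_rank[b], pc$width[b]))
  set <- makeClusterSet(sets, layout, "intersected", "TRU")
  set
}

#' Write a complete synthetic input bundle
#'
#' Generates all inputs under one config and writes them in the formats the
#' pipeline reads: layout GFF3, expression TSV, marked-gene list, duplicate
#' pairs TSV, RPKM TSV.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
simulateAll <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- simulateGenome(config)
  expr <- simulateExpression(config, layout)
  track <- simulateMarks(config, layout)
  dups <- simulateDuplicates(config, layout)
  rpkm <- simulateRpkm(config, layout)

  paths <- list(
    layout = file.path(dir, "genes.gff3"),
    expression = file.path(dir, "expression.tsv"),
    marks = file.path(dir, "marked_genes.txt"),
    duplicates = file.path(dir, "duplicates.tsv"),
    rpkm = file.path(dir, "rpkm.tsv"))

  gr <- layoutAsGRanges(layout)
  gr$type <- "gene"
  gr$ID <- gr$gene_id
  gr$rank <- NULL
  rtracklayer::export(gr, paths$layout, format = "GFF3")

  writeTsv(data.frame(gene_id = rownames(expr), round(expr, 6),
                      check.names = FALSE, stringsAsFactors = FALSE),
           paths$expression, c(n_samples = ncol(expr)))
  writeLines(c(outputHeader(), markedGenes(track)), paths$marks)
  writeDuplicatePairs(dups$loose, dups$strict, paths$duplicates)
  writeRpkmTable(rpkm, paths$rpkm)
  invisible(paths)
}
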