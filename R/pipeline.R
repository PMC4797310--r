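# End-to-end orchestration: read inputs, build the banded graph, call
# clusters, detect mark runs, intersect and filter, optionally scan mutant
# RPKM, and write every intermediate plus a JSON manifest.

#' Assemble a pipeline configuration
#'
#' Paths to the five inputs plus the mining parameters. Defaults are the
#' reference parameterization: window g = 10 genes, PCC cutoff c = 0.65,
#' mark runs of >= 4 genes, clusters of >= 3 genes, >= 3 gene-family types,
#' 2-fold mis-regulation in >= 3 mutants.
#'
#' @param layout path to a GFF3/BED annotation or a layout TSV written by
#'   \code{\link{writeGenomeLayout}}.
#' @param expression path to the log2 expression TSV.
#' @param marks path to the marked-gene list (or BED).
#' @param duplicates path to the duplicate-pairs TSV (both tiers).
#' @param rpkm optional path to the RPKM TSV; NULL skips the
#'   mis-regulation scan.
#' @param outDir output directory.
#' @param wildType wild-type genotype name in the RPKM table.
#' @param g,c banded-graph window and PCC cutoff.
#' @param minRun minimum marked-run length (genes).
#' @param minSize minimum co-expressed cluster size (nodes).
#' @param minCoexprMarked minimum marked members at intersection.
#' @param minTypes minimum gene-family types after the tandem filter.
#' @param fold mis-regulation fold-change threshold.
#' @param minGenes minimum mis-regulated stretch length.
#' @param minMutants minimum mutants showing the change.
#' @param nShuffles permutation replicates for the two nulls (0 skips them).
#' @param seed integer seed for the permutation nulls.
#' @return a validated configuration list (class \code{"PipelineConfig"}).
#' @export
pipelineConfig <- function(layout, expression, marks, duplicates,
                           rpkm = NULL, outDir = "mgcminer_out",
                           wildType = "Col0",
                           g = 10L, c = 0.65, minRun = 4L, minSize = 3L,
                           minCoexprMarked = 3L, minTypes = 3L,
                           fold = 2, minGenes = 3L, minMutants = 3L,
                           nShuffles = 0L, seed = 1L) {
  stopifnot(g >= 1L, c > -1, c <= 1, minRun >= 1L, minSize >= 1L,
            minTypes >= 1L, fold > 0, minGenes >= 1L, minMutants >= 1L,
            nShuffles >= 0L)
  cfg <- list(layout = layout, expression = expression, marks = marks,
              duplicates = duplicates, rpkm = rpkm, outDir = outDir,
              wildType = wildType, g = as.integer(g), c = as.numeric(c),
              minRun = as.integer(minRun), minSize = as.integer(minSize),
              minCoexprMarked = as.integer(minCoexprMarked),
              minTypes = as.integer(minTypes), fold = as.numeric(fold),
              minGenes = as.integer(minGenes),
              minMutants = as.integer(minMutants),
              nShuffles = as.integer(nShuffles), seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of \code{\link{pipelineConfig}}.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, vals)
}

# Internal: run one stage with a stage-named error.
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full mining pipeline
#'
#' Executes graph construction, cluster calling (both methods), mark-run
#' detection, the intersection and tandem-array filters and, when an RPKM
#' table is configured, the mutant mis-regulation scan. Optionally runs the
#' two permutation nulls. Writes every intermediate artifact as TSV plus a
#' JSON manifest recording parameter values, input checksums, the seed, and
#' per-stage counts. Re-running with identical inputs reproduces
#' byte-identical outputs.
#'
#' @param config a \code{"PipelineConfig"} from \code{\link{pipelineConfig}}.
#' @return the manifest, invisibly (also written to
#'   \code{outDir/manifest.json}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  for (what in c("layout", "expression", "marks", "duplicates", "rpkm")) {
    p <- config[[what]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("stage '%s' failed: input file not found: %s", what, p),
           call. = FALSE)
  }
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  layout <- stage("layout", {
    if (grepl("\\.(gff3?|bed)$", config$layout, ignore.case = TRUE))
      loadGenomeLayout(config$layout)
    else readGenomeLayout(config$layout)
  })
  expr <- stage("expression", readExpressionMatrix(config$expression))
  track <- stage("marks", readMarkTrack(config$marks, layout))
  dups <- stage("duplicates", readDuplicatePairs(config$duplicates))

  pcc <- stage("graph", bandedPCC(expr, layout, config$g))
  graph <- stage("graph", buildGeneGraph(pcc, config$c, dups$loose))
  clique <- stage("clusters", cliqueClusters(graph, layout, config$minSize))
  comp <- stage("clusters", componentClusters(graph, layout, config$minSize))
  runs <- stage("mark_runs", findMarkRuns(track, layout, config$minRun))
  cand <- stage("intersect",
                intersectClusters(clique, track, layout,
                                  minMarkedRun = config$minRun,
                                  minCoexprMarked = config$minCoexprMarked))
  final <- stage("tandem_filter",
                 filterTandemArrays(cand, dups$strict, config$minTypes))

  misreg <- NULL
  if (!is.null(config$rpkm)) {
    misreg <- stage("misregulation", {
      rpkm <- readRpkmTable(config$rpkm, config$wildType)
      fc <- foldChanges(rpkm)
      findMisregulatedRegions(fc, layout, minGenes = config$minGenes,
                              minAbsLog2fc = log2(config$fold),
                              minMutants = config$minMutants)
    })
  }

  nulls <- NULL
  if (config$nShuffles > 0L) {
    nulls <- stage("permutation_nulls", {
      markNull <- shuffleMarkNull(track, layout, config$minRun,
                                  config$nShuffles, config$seed)
      orderNull <- shuffleGeneOrderNull(expr, layout, dups$loose,
                                        config$g, config$c, "clique",
                                        config$nShuffles, config$seed,
                                        config$minSize)
      list(mark = markNull, gene_order = orderNull)
    })
  }

  out <- function(f) file.path(config$outDir, f)
  writeGenomeLayout(layout, out("layout.tsv"))
  writeClusterSet(clique, out("clusters_clique.tsv"))
  writeClusterSet(comp, out("clusters_component.tsv"))
  writeTsv(runs, out("mark_runs.tsv"), c(min_run = config$minRun))
  writeClusterSet(cand, out("clusters_intersected.tsv"))
  writeClusterSet(final, out("clusters_final.tsv"))
  writeClusterSet(final, out("clusters_final.json"), format = "json")
  if (!is.null(misreg)) writeClusterSet(misreg, out("misregulated_regions.tsv"))

  inputs <- Filter(Negate(is.null),
                   config[c("layout", "expression", "marks", "duplicates", "rpkm")])
  manifest <- list(
    package = "mgcMiner",
    version = as.character(utils::packageVersion("mgcMiner")),
    parameters = config[c("g", "c", "minRun", "minSize", "minCoexprMarked",
                          "minTypes", "fold", "minGenes", "minMutants",
                          "nShuffles", "seed", "wildType")],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    counts = list(
      genes = nGenes(layout),
      expressed_genes = length(attr(pcc, "universe")),
      edges = igraph::ecount(graph@graph),
      clique_clusters = nClusters(clique),
      component_clusters = nClusters(comp),
      mark_runs = nrow(runs),
      marked_genes = nMarked(track),
      intersected = nClusters(cand),
      final_clusters = nClusters(final),
      misregulated_regions = if (is.null(misreg)) NULL else nClusters(misreg)),
    nulls = if (is.null(nulls)) NULL else lapply(nulls, function(x)
      list(observed = x@observed, mean = x@mean, sd = x@sd, z = x@z,
           p_normal = x@pNormal, p_empirical = x@pEmpirical)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  message(sprintf(
    "mgcMiner: %d genes, %d edges; %d clique / %d component clusters; %d mark runs; %d intersected -> %d final clusters",
    manifest$counts$genes, manifest$counts$edges,
    manifest$counts$clique_clusters, manifest$counts$component_clusters,
    manifest$counts$mark_runs, manifest$counts$intersected,
    manifest$counts$final_clusters))
  invisible(manifest)
}
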