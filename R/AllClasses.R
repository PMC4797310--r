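#' GenomeLayout: ordered genes per chromosome
#'
#' The coordinate system every pipeline stage shares. Genes are ordered within
#' each chromosome by ascending start coordinate (ties broken by gene ID) and
#' assigned a 0-based integer \emph{rank}. All "within g genes" and
#' "contiguous" semantics are defined on ranks; ranks never compare across
#' chromosomes.
#'
#' @slot genes data.frame with columns \code{chrom}, \code{gene_id},
#'   \code{start}, \code{end}, \code{strand}, \code{rank}, sorted by
#'   (chromosome, rank).
#' @slot chromosomes character vector giving chromosome order.
#' @export
setClass("GenomeLayout",
  representation(genes = "data.frame", chromosomes = "character"),
  validity = function(object) {
    g <- object@genes
    need <- c("chrom", "gene_id", "start", "end", "strand", "rank")
    if (!all(need %in% names(g)))
      return(paste("genes must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(g$gene_id))
      return("gene IDs must be unique genome-wide")
    if (!all(g$chrom %in% object@chromosomes))
      return("genes on chromosomes absent from the chromosome list")
    for (ch in object@chromosomes) {
      r <- g$rank[g$chrom == ch]
      if (length(r) == 0L) return(sprintf("chromosome '%s' has no genes", ch))
      if (!identical(sort(r), seq_along(r) - 1L))
        return(sprintf("ranks on '%s' are not 0..n-1 without gaps", ch))
    }
    TRUE
  }
)

#' DuplicatePairs: homologous gene pairs at one similarity tier
#'
#' Unordered, deduplicated gene-ID pairs standing in for BLASTn hits: the
#' \code{loose} tier corresponds to e-value < 0.2 (used to strip trivially
#' correlated homolog edges from the co-expression graph) and the
#' \code{strict} tier to e-value < 0.01 (used to group tandem-array members
#' into gene families).
#'
#' @slot pairs two-column character matrix, each row a pair with
#'   \code{pairs[,1] < pairs[,2]}.
#' @slot tier \code{"loose"} or \code{"strict"}.
#' @export
setClass("DuplicatePairs",
  representation(pairs = "matrix", tier = "character"),
  validity = function(object) {
    p <- object@pairs
    if (ncol(p) != 2L) return("pairs must have two columns")
    if (!is.character(p[0, ]) && nrow(p) > 0 && !is.character(p))
      return("pairs must be a character matrix")
    if (nrow(p) > 0 && any(p[, 1] == p[, 2])) return("self-pairs not allowed")
    if (nrow(p) > 0 && any(p[, 1] > p[, 2]))
      return("pairs must be canonically ordered (first < second)")
    if (!object@tier %in% c("loose", "strict"))
      return("tier must be 'loose' or 'strict'")
    TRUE
  }
)

#' GeneGraph: the banded co-expression graph
#'
#' Undirected, unweighted graph whose nodes are genes and whose edges join
#' same-chromosome genes within \code{g} ranks of each other whose expression
#' profiles correlate at PCC >= \code{c}, after removal of loose-tier
#' duplicate pairs.
#'
#' @slot graph an igraph object (undirected, simple).
#' @slot g integer rank window.
#' @slot c numeric PCC cutoff.
#' @export
setClass("GeneGraph",
  representation(graph = "ANY", g = "integer", c = "numeric"),
  validity = function(object) {
    if (!igraph::is_igraph(object@graph)) return("graph slot must be an igraph")
    if (igraph::is_directed(object@graph)) return("graph must be undirected")
    if (length(object@g) != 1L || object@g < 1L) return("g must be a single integer >= 1")
    if (length(object@c) != 1L || object@c <= -1 || object@c > 1)
      return("c must lie in (-1, 1]")
    TRUE
  }
)

#' GeneClusterSet: called gene clusters
#'
#' A set of clusters, each a node set on one chromosome with an enclosing
#' rank span (half-open, 0-based). Provenance records the calling method:
#' merged maximal cliques, connected components, chromatin-mark runs,
#' the co-expression/mark intersection, or the mutant mis-regulation scan.
#'
#' @slot clusters data.frame with columns \code{cluster_id}, \code{chrom},
#'   \code{start_rank}, \code{end_rank} (exclusive), \code{n_members},
#'   \code{members} (semicolon-joined gene IDs in rank order),
#'   \code{provenance}, plus optional annotation columns.
#' @export
setClass("GeneClusterSet",
  representation(clusters = "data.frame"),
  validity = function(object) {
    cl <- object@clusters
    need <- c("cluster_id", "chrom", "start_rank", "end_rank",
              "n_members", "members", "provenance")
    if (!all(need %in% names(cl)))
      return(paste("clusters must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(cl$cluster_id)) return("cluster IDs must be unique")
    if (nrow(cl) > 0 && any(cl$end_rank <= cl$start_rank))
      return("spans must be non-empty half-open intervals")
    ok <- cl$provenance %in% c("clique", "component", "mark_run",
                               "intersected", "misregulated")
    if (nrow(cl) > 0 && !all(ok)) return("unknown provenance")
    TRUE
  }
)

#' MarkTrack: per-gene binary chromatin-mark calls
#'
#' One boolean per gene, aligned to the ranks of a \linkS4class{GenomeLayout}
#' (e.g. H3K27me3 present/absent on the gene body).
#'
#' @slot marked named logical vector; names are gene IDs in layout order.
#' @export
setClass("MarkTrack",
  representation(marked = "logical"),
  validity = function(object) {
    if (is.null(names(object@marked))) return("marked must be named by gene ID")
    if (anyDuplicated(names(object@marked))) return("duplicated gene IDs")
    if (anyNA(object@marked)) return("mark states must not be NA")
    TRUE
  }
)

#' ShuffleNull: permutation-null summary
#'
#' Per-replicate counts from a seeded Fisher-Yates permutation null, with the
#' observed count, normal-approximation z and one-sided upper-tail p, and an
#' empirical p of (#replicates >= observed + 1) / (n + 1).
#'
#' @slot replicateCounts integer vector of per-replicate cluster/run counts.
#' @slot observed integer observed count.
#' @slot mean,sd numeric null mean and sample sd (denominator n-1).
#' @slot z,pNormal,pEmpirical numeric test summaries.
#' @slot seed integer seed used.
#' @slot statistic character label of the counted statistic.
#' @export
setClass("ShuffleNull",
  representation(replicateCounts = "integer", observed = "integer",
                 mean = "numeric", sd = "numeric", z = "numeric",
                 pNormal = "numeric", pEmpirical = "numeric",
                 seed = "integer", statistic = "character"),
  validity = function(object) {
    n <- length(object@replicateCounts)
    if (n < 2L) return("need at least 2 replicates")
    if (!isTRUE(all.equal(object@mean, mean(object@replicateCounts))))
      return("mean inconsistent with replicate counts")
    if (!isTRUE(all.equal(object@sd, stats::sd(object@replicateCounts))))
      return("sd inconsistent with replicate counts")
    if (!is.na(object@pNormal) && (object@pNormal < 0 || object@pNormal > 1))
      return("pNormal outside [0, 1]")
    TRUE
  }
)

#' RpkmTable: per-gene expression abundance across genotypes
#'
#' RPKM (reads per kilobase per million mapped reads) values for a wild type
#' and a set of mutant genotypes; input to the mis-regulation scan.
#'
#' @slot values non-negative numeric matrix, genes x genotypes.
#' @slot wildType column name of the wild-type genotype.
#' @export
setClass("RpkmTable",
  representation(values = "matrix", wildType = "character"),
  validity = function(object) {
    v <- object@values
    if (is.null(rownames(v)) || is.null(colnames(v)))
      return("values must have gene rownames and genotype colnames")
    if (!object@wildType %in% colnames(v))
      return("wild-type genotype absent from columns")
    if (any(!is.finite(v))) return("values must be finite")
    if (any(v < 0)) return("RPKM values must be non-negative")
    if (ncol(v) < 2L) return("need the wild type plus at least one mutant")
    TRUE
  }
)

#' SimulationConfig: parameters of the synthetic study generator
#'
#' Describes a synthetic genome with planted co-expressed gene blocks,
#' planted contiguous chromatin-mark runs, tandem-array duplicate families
#' and mutant genotypes with coordinate down-regulation of planted clusters.
#' Defaults (see \code{\link{simulationConfig}}) emulate the desk-scale study
#' conditions the pipeline is validated on.
#'
#' @slot nChromosomes,genesPerChromosome,nSamples integers.
#' @slot plantedClusters data.frame(chrom, start_rank, width, rho).
#' @slot plantedMarkRuns data.frame(chrom, start_rank, length).
#' @slot tandemArrays data.frame(chrom, start_rank, width, n_families, rho).
#' @slot backgroundMarkRate numeric in [0, 1].
#' @slot mutants character vector of mutant genotype names.
#' @slot wildType character wild-type genotype name.
#' @slot mutantEffects numeric matrix, planted clusters x mutants, log2 units.
#' @slot noiseSd numeric sd of multiplicative log2 noise on mutant RPKM.
#' @slot rpkmMeanlog,rpkmSdlog numeric log-normal parameters of wild-type RPKM.
#' @slot extraLoosePairs integer count of additional loose-only duplicate pairs.
#' @slot seed integer master seed.
#' @export
setClass("SimulationConfig",
  representation(nChromosomes = "integer", genesPerChromosome = "integer",
                 nSamples = "integer", plantedClusters = "data.frame",
                 plantedMarkRuns = "data.frame", tandemArrays = "data.frame",
                 backgroundMarkRate = "numeric", mutants = "character",
                 wildType = "character", mutantEffects = "matrix",
                 noiseSd = "numeric", rpkmMeanlog = "numeric",
                 rpkmSdlog = "numeric", extraLoosePairs = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (object@nChromosomes < 1L) return("need at least one chromosome")
    if (object@genesPerChromosome < 1L) return("genesPerChromosome must be >= 1")
    if (object@nSamples < 3L) return("need at least 3 expression samples")
    if (object@backgroundMarkRate < 0 || object@backgroundMarkRate > 1)
      return("backgroundMarkRate must lie in [0, 1]")
    pc <- object@plantedClusters
    if (nrow(pc) > 0 && (any(pc$rho < 0) || any(pc$rho > 1)))
      return("within-cluster correlation rho must lie in [0, 1]")
    m <- object@genesPerChromosome
    fits <- function(chrom, start, len)
      all(chrom >= 1L & chrom <= object@nChromosomes & start >= 0L &
            start + len <= m)
    if (nrow(pc) > 0 && !fits(pc$chrom, pc$start_rank, pc$width))
      return("a planted cluster does not fit on its chromosome")
    pr <- object@plantedMarkRuns
    if (nrow(pr) > 0 && !fits(pr$chrom, pr$start_rank, pr$length))
      return("a planted mark run does not fit on its chromosome")
    ta <- object@tandemArrays
    if (nrow(ta) > 0 && !fits(ta$chrom, ta$start_rank, ta$width))
      return("a tandem array does not fit on its chromosome")
    if (nrow(ta) > 0 && any(ta$n_families < 1L | ta$n_families > ta$width))
      return("n_families must lie in [1, width]")
    if (nrow(object@mutantEffects) != nrow(pc) ||
        ncol(object@mutantEffects) != length(object@mutants))
      return("mutantEffects must be planted-clusters x mutants")
    feats <- rbind(
      data.frame(chrom = pc$chrom, start = pc$start_rank, len = pc$width),
      data.frame(chrom = ta$chrom, start = ta$start_rank, len = ta$width))
    if (nrow(feats) > 1) {
      o <- order(feats$chrom, feats$start)
      feats <- feats[o, ]
      same <- feats$chrom[-1] == feats$chrom[-nrow(feats)]
      overl <- feats$start[-1] < (feats$start + feats$len)[-nrow(feats)]
      if (any(same & overl))
        return("planted expression features (clusters/arrays) overlap")
    }
    TRUE
  }
)
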