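# Cluster calling: merged maximal cliques (stringent) and connected
# components (relaxed), plus the gene-order permutation null.

# Internal: build a GeneClusterSet from a list of member-ID sets.
makeClusterSet <- function(memberSets, layout, provenance, prefix) {
  if (length(memberSets) == 0L)
    return(methods::new("GeneClusterSet", clusters = data.frame(
      cluster_id = character(0), chrom = character(0),
      start_rank = integer(0), end_rank = integer(0),
      n_members = integer(0), members = character(0),
      provenance = character(0), stringsAsFactors = FALSE)))
  tab <- layout@genes
  rows <- lapply(memberSets, function(m) {
    i <- match(m, tab$gene_id)
    if (anyNA(i)) stop("cluster member(s) absent from layout")
    ch <- unique(tab$chrom[i])
    if (length(ch) != 1L) stop("cluster spans multiple chromosomes")
    o <- order(tab$rank[i])
    data.frame(chrom = ch,
               start_rank = min(tab$rank[i]),
               end_rank = max(tab$rank[i]) + 1L,
               n_members = length(m),
               members = paste(m[o], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  o <- order(match(df$chrom, layout@chromosomes), df$start_rank, df$end_rank)
  df <- df[o, , drop = FALSE]
  df$cluster_id <- sprintf("%s%03d", prefix, seq_len(nrow(df)))
  df$provenance <- provenance
  rownames(df) <- NULL
  methods::new("GeneClusterSet", clusters = df[, c(
    "cluster_id", "chrom", "start_rank", "end_rank", "n_members",
    "members", "provenance")])
}

#' @describeIn GeneClusterSet number of clusters.
#' @param x,object a \code{GeneClusterSet}.
#' @export
setMethod("nClusters", "GeneClusterSet", function(x) nrow(x@clusters))

#' @describeIn GeneClusterSet member gene IDs as a named list of character
#'   vectors (rank order).
#' @export
setMethod("clusterMembers", "GeneClusterSet", function(x) {
  stats::setNames(strsplit(x@clusters$members, ";", fixed = TRUE),
                  x@clusters$cluster_id)
})

#' @describeIn GeneClusterSet show a summary.
#' @export
setMethod("show", "GeneClusterSet", function(object) {
  cl <- object@clusters
  cat(sprintf("GeneClusterSet: %d cluster(s)%s\n", nrow(cl),
              if (nrow(cl)) sprintf(" [%s]",
                paste(unique(cl$provenance), collapse = ", ")) else ""))
  if (nrow(cl)) {
    sizes <- cl$n_members
    cat(sprintf("  members: median %g, range %d-%d\n",
                stats::median(sizes), min(sizes), max(sizes)))
  }
})

#' Cluster table accessor
#'
#' @param x a \linkS4class{GeneClusterSet}.
#' @return the underlying data.frame.
#' @export
clusterTable <- function(x) x@clusters

# Internal: merged-maximal-clique member sets (>= minSize), as the count or
# the sets themselves. Maximal cliques sharing any node are grouped into one
# cluster by transitive closure.
mergedCliqueSets <- function(gr, minSize = 3L) {
  cl <- igraph::max_cliques(gr, min = minSize)
  if (length(cl) == 0L) return(list())
  names(cl) <- NULL
  nodeNames <- igraph::V(gr)$name
  idx <- lapply(cl, as.integer)
  # union-find over cliques via shared nodes
  owner <- integer(igraph::vcount(gr))  # 0 = unseen; else clique-group id
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(idx)) {
    for (v in idx[[k]]) {
      if (owner[v] == 0L) owner[v] <- k
      else parent[find(k)] <- find(owner[v])
    }
  }
  grp <- vapply(seq_along(idx), find, integer(1))
  sets <- lapply(split(idx, grp), function(l) sort(unique(unlist(l))))
  lapply(sets, function(i) nodeNames[i])
}

#' Call clusters by merged maximal cliques
#'
#' Enumerates maximal cliques (Bron-Kerbosch with pivoting) of at least
#' \code{minSize} nodes and merges cliques sharing any node into one cluster
#' (transitive closure). The stringent calling method.
#'
#' @param graph a \linkS4class{GeneGraph}.
#' @param layout a \linkS4class{GenomeLayout}.
#' @param minSize minimum clique size (default 3).
#' @return a \linkS4class{GeneClusterSet} with provenance \code{"clique"}.
#' @export
cliqueClusters <- function(graph, layout, minSize = 3L) {
  sets <- mergedCliqueSets(graph@graph, minSize)
  makeClusterSet(sets, layout, "clique", "CLQ")
}

#' Call clusters by connected components
#'
#' Components of at least \code{minSize} nodes; each node need only connect
#' to one other. The relaxed ("subgraph") calling method.
#'
#' @inheritParams cliqueClusters
#' @return a \linkS4class{GeneClusterSet} with provenance \code{"component"}.
#' @export
componentClusters <- function(graph, layout, minSize = 3L) {
  comp <- igraph::components(graph@graph)
  keep <- which(comp$csize >= minSize)
  nodeNames <- igraph::V(graph@graph)$name
  sets <- lapply(keep, function(k) nodeNames[comp$membership == k])
  makeClusterSet(sets, layout, "component", "CMP")
}

# Internal: cluster count for one graph under a method.
countClusters <- function(gr, method, minSize = 3L) {
  if (method == "clique") length(mergedCliqueSets(gr, minSize))
  else sum(igraph::components(gr)$csize >= minSize)
}

# Internal: assemble a ShuffleNull from replicate counts.
newShuffleNull <- function(counts, observed, seed, statistic) {
  counts <- as.integer(counts)
  m <- mean(counts); s <- stats::sd(counts)
  z <- if (s > 0) (observed - m) / s else NA_real_
  pN <- if (is.na(z)) NA_real_ else stats::pnorm(z, lower.tail = FALSE)
  pE <- (sum(counts >= observed) + 1) / (length(counts) + 1)
  methods::new("ShuffleNull", replicateCounts = counts,
               observed = as.integer(observed), mean = m, sd = s, z = z,
               pNormal = pN, pEmpirical = pE, seed = as.integer(seed),
               statistic = statistic)
}

#' Display a permutation-null summary
#' @param object a \linkS4class{ShuffleNull}.
#' @keywords internal
#' @export
setMethod("show", "ShuffleNull", function(object) {
  cat(sprintf(paste0(
    "ShuffleNull (%s): observed %d vs null mean %.2f, sd %.2f ",
    "(%d replicates)\n  z = %.2f, one-sided normal p = %.3g, empirical p = %.3g\n"),
    object@statistic, object@observed, object@mean, object@sd,
    length(object@replicateCounts), object@z, object@pNormal,
    object@pEmpirical))
})

#' Gene-order permutation null for co-expressed cluster counts
#'
#' Shuffles the gene order independently within each chromosome
#' (Fisher-Yates), rebuilds the banded graph from the same correlation
#' values re-indexed by the new ranks (each gene keeps its expression row
#' and duplicate relations), recalls clusters, and records the count per
#' replicate. Only physical adjacency is randomized; (g, c) stay fixed at
#' the observed-data values.
#'
#' @param expr log2 expression matrix.
#' @param layout a \linkS4class{GenomeLayout}.
#' @param duplicates loose-tier \linkS4class{DuplicatePairs} or NULL.
#' @param g,c graph parameters.
#' @param method \code{"clique"} or \code{"component"}.
#' @param nShuffles number of replicates (>= 2).
#' @param seed integer seed.
#' @param minSize minimum cluster size.
#' @return a \linkS4class{ShuffleNull}.
#' @export
shuffleGeneOrderNull <- function(expr, layout, duplicates = NULL, g, c,
                                 method = c("clique", "component"),
                                 nShuffles = 100L, seed = 1L, minSize = 3L) {
  method <- match.arg(method)
  stopifnot(nShuffles >= 2L)
  observed <- {
    pcc <- bandedPCC(expr, layout, g)
    gr <- buildGeneGraph(pcc, c, duplicates)
    countClusters(gr@graph, method, minSize)
  }
  common <- intersect(geneIds(layout), rownames(expr))
  scaled <- scaleRows(expr[common, , drop = FALSE])
  universe <- rownames(scaled)
  chromGenes <- chromGeneList(layout)
  dupKeys <- if (!is.null(duplicates))
    pairKey(duplicates@pairs[, 1], duplicates@pairs[, 2]) else character(0)
  counts <- withSeed(seed, vapply(seq_len(nShuffles), function(i) {
    ordered <- lapply(chromGenes, function(ids) ids[sample.int(length(ids))])
    band <- bandedPCCOrdered(scaled, ordered, g)
    keep <- band$pcc >= c
    if (length(dupKeys))
      keep <- keep & !(pairKey(band$gene_a, band$gene_b) %in% dupKeys)
    edges <- data.frame(from = band$gene_a[keep], to = band$gene_b[keep],
                        stringsAsFactors = FALSE)
    gr <- igraph::simplify(igraph::graph_from_data_frame(
      edges, directed = FALSE, vertices = data.frame(name = universe)))
    countClusters(gr, method, minSize)
  }, numeric(1)))
  newShuffleNull(counts, observed, seed,
                 sprintf("%s clusters, gene-order shuffle", method))
}

#' Write a cluster set to TSV or JSON
#'
#' @param x a \linkS4class{GeneClusterSet}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
writeClusterSet <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    writeTsv(x@clusters, path, c(n_clusters = nrow(x@clusters)))
  } else {
    jsonlite::write_json(x@clusters, path, dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' Read a cluster set written by \code{writeClusterSet}
#'
#' @param path TSV path.
#' @return a \linkS4class{GeneClusterSet}.
#' @export
readClusterSet <- function(path) {
  df <- readTsv(path)
  df$members <- as.character(df$members)
  methods::new("GeneClusterSet", clusters = df)
}
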