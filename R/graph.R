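#' Construct DuplicatePairs
#'
#' @param pairs two-column matrix or data.frame of gene IDs; order within a
#'   pair is irrelevant, duplicates and self-pairs are removed/rejected.
#' @param tier \code{"loose"} (BLASTn e < 0.2 stand-in, graph edge removal)
#'   or \code{"strict"} (e < 0.01, gene-family grouping).
#' @return a \linkS4class{DuplicatePairs}.
#' @export
DuplicatePairs <- function(pairs, tier = c("loose", "strict")) {
  tier <- match.arg(tier)
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  if (length(pairs) == 0L)
    pairs <- matrix(character(0), ncol = 2)
  mode(pairs) <- "character"
  if (nrow(pairs) > 0) {
    if (any(pairs[, 1] == pairs[, 2])) stop("self-pairs not allowed")
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    pairs <- pairs[!duplicated(paste(pairs[, 1], pairs[, 2], sep = "\r")), ,
                   drop = FALSE]
  }
  colnames(pairs) <- c("gene_a", "gene_b")
  methods::new("DuplicatePairs", pairs = pairs, tier = tier)
}

#' @describeIn DuplicatePairs the tier label.
#' @param x,object a \code{DuplicatePairs}.
#' @export
setMethod("duplicateTier", "DuplicatePairs", function(x) x@tier)

#' @describeIn DuplicatePairs show a summary.
#' @export
setMethod("show", "DuplicatePairs", function(object) {
  cat(sprintf("DuplicatePairs: %d %s-tier pair(s)\n",
              nrow(object@pairs), object@tier))
})

#' Read duplicate pairs from TSV
#'
#' Expects columns gene_a, gene_b, tier where tier records the strictest
#' level a pair attains ("strict" = BLASTn e < 0.01, "loose" = e < 0.2).
#' Since strict pairs are a subset of loose pairs, the loose object contains
#' every pair in the file and the strict object only the strict rows.
#'
#' @param path TSV path.
#' @return list with elements \code{loose} and \code{strict}, each a
#'   \linkS4class{DuplicatePairs}.
#' @export
readDuplicatePairs <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("gene_a", "gene_b", "tier") %in% names(df)))
  if (!all(df$tier %in% c("loose", "strict")))
    stop("tier column must be 'loose' or 'strict'")
  list(loose = DuplicatePairs(df[, c("gene_a", "gene_b")], "loose"),
       strict = DuplicatePairs(df[df$tier == "strict", c("gene_a", "gene_b")],
                               "strict"))
}

#' Write both duplicate tiers to one TSV
#'
#' @param loose,strict \linkS4class{DuplicatePairs} of the respective tiers;
#'   strict pairs must be a subset of loose pairs.
#' @param path output path.
#' @export
writeDuplicatePairs <- function(loose, strict, path) {
  stopifnot(duplicateTier(loose) == "loose", duplicateTier(strict) == "strict")
  lk <- pairKey(loose@pairs[, 1], loose@pairs[, 2])
  sk <- pairKey(strict@pairs[, 1], strict@pairs[, 2])
  if (!all(sk %in% lk)) stop("strict pairs must be a subset of loose pairs")
  df <- data.frame(gene_a = loose@pairs[, 1], gene_b = loose@pairs[, 2],
                   tier = ifelse(lk %in% sk, "strict", "loose"),
                   stringsAsFactors = FALSE)
  writeTsv(df, path, c(n_pairs = nrow(df)))
}

#' Build the banded co-expression graph
#'
#' An edge joins a gene pair when its banded PCC meets the cutoff
#' (inclusive, PCC >= c) and the pair is not a loose-tier duplicate.
#' Nodes are all genes of the band universe (expressed, non-degenerate
#' layout genes), so isolated genes are represented.
#'
#' @param pcc output of \code{\link{bandedPCC}}.
#' @param c PCC cutoff in (-1, 1].
#' @param duplicates optional loose-tier \linkS4class{DuplicatePairs} whose
#'   edges are removed.
#' @return a \linkS4class{GeneGraph}.
#' @export
buildGeneGraph <- function(pcc, c, duplicates = NULL) {
  stopifnot(c > -1, c <= 1)
  universe <- attr(pcc, "universe")
  keep <- pcc$pcc >= c
  if (!is.null(duplicates)) {
    if (duplicateTier(duplicates) != "loose")
      warning("removing duplicate edges with tier '", duplicateTier(duplicates),
              "'; the loose tier (e < 0.2) is the intended input")
    dup <- pairKey(pcc$gene_a, pcc$gene_b) %in%
      pairKey(duplicates@pairs[, 1], duplicates@pairs[, 2])
    keep <- keep & !dup
  }
  edges <- pcc[keep, c("gene_a", "gene_b"), drop = FALSE]
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = data.frame(name = universe))
  gr <- igraph::simplify(gr)
  methods::new("GeneGraph", graph = gr, g = as.integer(attr(pcc, "g")),
               c = as.numeric(c))
}

#' @describeIn buildGeneGraph graph parameters as a named list.
#' @param x,object a \code{GeneGraph}.
#' @export
setMethod("graphParams", "GeneGraph", function(x) list(g = x@g, c = x@c))

#' @describeIn buildGeneGraph show a summary.
#' @export
setMethod("show", "GeneGraph", function(object) {
  cat(sprintf("GeneGraph: %d node(s), %d edge(s), g=%d, c=%g\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              object@g, object@c))
})

#' Average clustering coefficient
#'
#' Mean local clustering coefficient (triangles through a node over pairs of
#' its neighbours), averaged over non-isolated nodes; nodes of degree < 2
#' contribute 0. An edgeless graph scores 0. Used as the "graph complexity"
#' objective when selecting the window g and cutoff c.
#'
#' @param graph a \linkS4class{GeneGraph} or igraph.
#' @param allNodes average over all nodes (isolated ones contribute 0)
#'   instead of non-isolated nodes only.
#' @return numeric in [0, 1].
#' @export
averageClusteringCoefficient <- function(graph, allNodes = FALSE) {
  g <- if (methods::is(graph, "GeneGraph")) graph@graph else graph
  if (igraph::ecount(g) == 0L) return(0)
  lcc <- igraph::transitivity(g, type = "local", isolates = "zero")
  deg <- igraph::degree(g)
  if (allNodes) mean(lcc) else mean(lcc[deg >= 1L])
}

#' Select the window g and PCC cutoff c by ACC maximization
#'
#' Evaluates the average clustering coefficient over a grid of (g, c) values
#' and returns the maximizing pair. The banded correlations are computed once
#' at the largest g and subset per grid point, so the search is deterministic
#' and cheap. Ties are broken toward the smallest g, then the largest c
#' (the most local, most stringent graph).
#'
#' @param expr log2 expression matrix.
#' @param layout a \linkS4class{GenomeLayout}.
#' @param duplicates loose-tier \linkS4class{DuplicatePairs} (or NULL).
#' @param gGrid integer window candidates.
#' @param cGrid numeric cutoff candidates in (-1, 1].
#' @param allNodes passed to \code{\link{averageClusteringCoefficient}}.
#' @return list(g, c, acc, surface) where surface is a gGrid x cGrid matrix.
#' @export
optimizeParameters <- function(expr, layout, duplicates = NULL,
                               gGrid = 1:15, cGrid = seq(0.5, 0.9, by = 0.05),
                               allNodes = FALSE) {
  stopifnot(length(gGrid) >= 1L, length(cGrid) >= 1L)
  gGrid <- sort(unique(as.integer(gGrid)))
  cGrid <- sort(unique(as.numeric(cGrid)))
  pcc <- bandedPCC(expr, layout, g = max(gGrid))
  surface <- matrix(NA_real_, length(gGrid), length(cGrid),
                    dimnames = list(g = gGrid, c = cGrid))
  best <- list(g = gGrid[1], c = max(cGrid), acc = -Inf)
  for (gi in seq_along(gGrid)) {
    sub <- pcc[pcc$distance <= gGrid[gi], , drop = FALSE]
    attr(sub, "universe") <- attr(pcc, "universe")
    attr(sub, "g") <- gGrid[gi]
    for (ci in rev(seq_along(cGrid))) {
      gr <- buildGeneGraph(sub, cGrid[ci], duplicates)
      acc <- averageClusteringCoefficient(gr, allNodes = allNodes)
      surface[gi, ci] <- acc
      if (acc > best$acc) best <- list(g = gGrid[gi], c = cGrid[ci], acc = acc)
    }
  }
  if (all(surface == 0))
    warning("ACC surface is identically zero; returning tie-break point")
  list(g = best$g, c = best$c, acc = max(best$acc, 0), surface = surface)
}
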