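# Shared fixture builders and brute-force oracles.

# A layout from parallel vectors; defaults to one chromosome with genes at
# 1kb spacing in the order given.
tinyLayout <- function(ids, chrom = "chr1", start = NULL) {
  if (is.null(start)) start <- seq_along(ids) * 1000L
  mgcMiner::GenomeLayout(data.frame(
    chrom = chrom, gene_id = ids, start = start, end = start + 500L,
    strand = "+", stringsAsFactors = FALSE))
}

# A GeneGraph over explicit edges (two-column matrix/data.frame of gene IDs).
tinyGraph <- function(nodes, edges, g = 10L, c = 0.5) {
  gr <- igraph::graph_from_data_frame(
    as.data.frame(edges), directed = FALSE,
    vertices = data.frame(name = nodes))
  methods::new("GeneGraph", graph = igraph::simplify(gr),
               g = as.integer(g), c = c)
}

# Brute-force average clustering coefficient: count triangles per node.
bruteACC <- function(graph, allNodes = FALSE) {
  g <- if (methods::is(graph, "GeneGraph")) graph@graph else graph
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0L) return(0)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  lcc <- numeric(n)
  deg <- rowSums(adj)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) next
    tri <- 0
    for (i in seq_along(nb)) for (j in seq_len(i - 1L))
      tri <- tri + adj[nb[i], nb[j]]
    lcc[v] <- tri / choose(length(nb), 2)
  }
  if (allNodes) mean(lcc) else mean(lcc[deg >= 1])
}

# Brute-force expectation of maximal runs of length >= r over all C(n, k)
# placements of k marks in n positions; returns a vector indexed by r = 1..n.
bruteExpectedRuns <- function(n, k) {
  if (k == 0L) return(numeric(n))
  subsets <- utils::combn(n, k)
  tot <- numeric(n)
  for (j in seq_len(ncol(subsets))) {
    pos <- subsets[, j]
    lens <- rle(cumsum(c(1L, diff(pos) != 1L)))$lengths
    for (r in seq_len(n)) tot[r] <- tot[r] + sum(lens >= r)
  }
  tot / ncol(subsets)
}

# Member sets of a cluster set, as a character vector of ";"-joined IDs.
memberKeys <- function(clusterSet) {
  unname(vapply(mgcMiner::clusterMembers(clusterSet), paste, character(1),
                collapse = ";"))
}

# Small config helper with no planted features.
emptyFeatures <- function() list(
  clusters = data.frame(chrom = integer(0), start_rank = integer(0),
                        width = integer(0), rho = numeric(0)),
  runs = data.frame(chrom = integer(0), start_rank = integer(0),
                    length = integer(0)),
  arrays = data.frame(chrom = integer(0), start_rank = integer(0),
                      width = integer(0), n_families = integer(0),
                      rho = numeric(0)))
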