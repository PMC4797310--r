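# Intersection of co-expressed clusters with chromatin-mark runs, and
# elimination of tandem arrays with too few gene-family types. The funnel
# that turns graph clusters into final candidate metabolic gene clusters.

#' Intersect co-expressed clusters with marked-gene runs
#'
#' A co-expressed cluster survives when (a) its enclosing rank span contains
#' at least \code{minMarkedRun} contiguous marked genes -- that is, a
#' contiguous marked segment of that length lies wholly within the span --
#' and (b) at least \code{minCoexprMarked} of the cluster's member genes are
#' themselves marked. Spans are used because clique members need not be
#' rank-contiguous; the graph only bounds pairwise separation.
#'
#' @param coexpr a \linkS4class{GeneClusterSet} (normally clique provenance,
#'   the stringent method).
#' @param track a \linkS4class{MarkTrack}.
#' @param layout the shared \linkS4class{GenomeLayout}.
#' @param runs optional precomputed \code{\link{findMarkRuns}} table of
#'   maximal runs (any length); recomputed from the track when NULL.
#' @param minMarkedRun minimum contiguous marked genes within the span.
#' @param minCoexprMarked minimum marked cluster members.
#' @return a \linkS4class{GeneClusterSet} with provenance
#'   \code{"intersected"} and annotation columns \code{marked_contiguous},
#'   \code{coexpressed_marked}, \code{family_types} (NA until the tandem
#'   filter runs) and \code{source_cluster}.
#' @export
intersectClusters <- function(coexpr, track, layout, runs = NULL,
                              minMarkedRun = 4L, minCoexprMarked = 3L) {
  checkAligned(track, layout)
  if (is.null(runs)) runs <- findMarkRuns(track, layout, minRun = 1L)
  cl <- clusterTable(coexpr)
  members <- clusterMembers(coexpr)
  markedContig <- integer(nrow(cl))
  markedMembers <- integer(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    r <- runs[runs$chrom == cl$chrom[i], , drop = FALSE]
    if (nrow(r)) {
      ov <- pmin(r$end_rank, cl$end_rank[i]) - pmax(r$start_rank, cl$start_rank[i])
      markedContig[i] <- max(0L, ov)
    }
    markedMembers[i] <- sum(track@marked[members[[i]]])
  }
  keep <- markedContig >= minMarkedRun & markedMembers >= minCoexprMarked
  df <- cl[keep, , drop = FALSE]
  if (nrow(df)) {
    df$provenance <- "intersected"
    df$source_cluster <- df$cluster_id
    df$cluster_id <- sprintf("MGC%03d", seq_len(nrow(df)))
    df$marked_contiguous <- markedContig[keep]
    df$coexpressed_marked <- markedMembers[keep]
    df$family_types <- NA_integer_
  } else {
    df$source_cluster <- character(0)
    df$marked_contiguous <- integer(0)
    df$coexpressed_marked <- integer(0)
    df$family_types <- integer(0)
  }
  rownames(df) <- NULL
  methods::new("GeneClusterSet", clusters = df)
}

#' Count gene families among a set of genes
#'
#' Families are connected components of the strict-tier duplicate relation
#' restricted to the given genes (transitive closure, so "gene type" is well
#' defined even when similarity is not transitive).
#'
#' @param genes character vector of gene IDs.
#' @param strictDuplicates strict-tier \linkS4class{DuplicatePairs}.
#' @return integer family count.
#' @export
countGeneFamilies <- function(genes, strictDuplicates) {
  p <- strictDuplicates@pairs
  sel <- p[, 1] %in% genes & p[, 2] %in% genes
  if (!any(sel)) return(length(genes))
  gr <- igraph::graph_from_data_frame(
    as.data.frame(p[sel, , drop = FALSE]), directed = FALSE,
    vertices = data.frame(name = genes))
  as.integer(igraph::components(gr)$no)
}

#' Eliminate tandem-array candidates with too few gene-family types
#'
#' Within each candidate, member genes are grouped into families by the
#' strict-tier duplicate relation (BLASTn e < 0.01 stand-in); candidates
#' whose members comprise fewer than \code{minTypes} distinct families --
#' i.e. regions consisting only of tandem arrays of one or two gene types --
#' are removed.
#'
#' @param candidates a \linkS4class{GeneClusterSet} from
#'   \code{\link{intersectClusters}}.
#' @param strictDuplicates strict-tier \linkS4class{DuplicatePairs}.
#' @param minTypes minimum distinct families (default 3, inclusive).
#' @return the filtered \linkS4class{GeneClusterSet} with
#'   \code{family_types} filled in.
#' @export
filterTandemArrays <- function(candidates, strictDuplicates, minTypes = 3L) {
  if (duplicateTier(strictDuplicates) != "strict")
    warning("family grouping expects the strict tier (e < 0.01)")
  df <- clusterTable(candidates)
  members <- clusterMembers(candidates)
  fam <- vapply(members, countGeneFamilies, integer(1),
                strictDuplicates = strictDuplicates)
  df$family_types <- if (nrow(df)) unname(fam) else integer(0)
  df <- df[df$family_types >= minTypes, , drop = FALSE]
  rownames(df) <- NULL
  methods::new("GeneClusterSet", clusters = df)
}
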