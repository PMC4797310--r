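# Mis-regulation scan: contiguous stretches of genes coordinately changed
# at least 2-fold in most chromatin-mutant genotypes relative to wild type.

#' Construct an RpkmTable
#'
#' @param values non-negative matrix, genes x genotypes (RPKM units).
#' @param wildType wild-type column name.
#' @return an \linkS4class{RpkmTable}.
#' @export
RpkmTable <- function(values, wildType) {
  methods::new("RpkmTable", values = values, wildType = wildType)
}

#' @describeIn RpkmTable show a summary.
#' @param object an \code{RpkmTable}.
#' @export
setMethod("show", "RpkmTable", function(object) {
  cat(sprintf("RpkmTable: %d genes x %d genotypes (wild type: %s)\n",
              nrow(object@values), ncol(object@values), object@wildType))
})

#' Read an RPKM table from TSV
#'
#' First column gene IDs, remaining columns one genotype each.
#'
#' @param path TSV path.
#' @param wildType wild-type genotype column name.
#' @return an \linkS4class{RpkmTable}.
#' @export
readRpkmTable <- function(path, wildType) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  RpkmTable(m, wildType)
}

#' Write an RPKM table to TSV
#'
#' @param table an \linkS4class{RpkmTable}.
#' @param path output path.
#' @export
writeRpkmTable <- function(table, path) {
  df <- data.frame(gene_id = rownames(table@values), table@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTsv(df, path, c(wild_type = table@wildType))
}

#' Per-gene, per-mutant log2 fold changes against wild type
#'
#' \code{log2((mutant + epsilon) / (wildtype + epsilon))}; the pseudocount
#' guards against division by zero at unexpressed genes and compresses fold
#' changes of weakly expressed genes toward zero.
#'
#' @param table an \linkS4class{RpkmTable}.
#' @param epsilon pseudocount added to both numerator and denominator
#'   (RPKM units, default 1).
#' @return matrix of log2 fold changes, genes x mutant genotypes.
#' @export
foldChanges <- function(table, epsilon = 1.0) {
  stopifnot(epsilon > 0)
  v <- table@values
  if (any(v < 0)) stop("negative RPKM values")
  wt <- v[, table@wildType]
  mut <- v[, setdiff(colnames(v), table@wildType), drop = FALSE]
  log2((mut + epsilon) / (wt + epsilon))
}

#' Find contiguous stretches of coordinately mis-regulated genes
#'
#' A gene qualifies in direction d (up or down) when its |log2 FC| is at
#' least \code{minAbsLog2fc} with sign d in at least \code{minMutants}
#' mutant genotypes. Maximal rank-contiguous stretches of at least
#' \code{minGenes} qualifying genes sharing one direction are reported;
#' stretches never cross chromosome boundaries. With
#' \code{sharedDirection = FALSE} the per-gene criterion counts 2-fold
#' changes of either sign and stretches mix directions.
#'
#' @param fc log2 fold-change matrix from \code{\link{foldChanges}}.
#' @param layout a \linkS4class{GenomeLayout}; genes absent from \code{fc}
#'   occupy ranks but never qualify (they break stretches).
#' @param minGenes minimum stretch length (default 3).
#' @param minAbsLog2fc minimum |log2 FC| (default 1, i.e. 2-fold).
#' @param minMutants minimum mutant genotypes showing the change (default 3).
#' @param sharedDirection require a single direction per stretch.
#' @return a \linkS4class{GeneClusterSet} with provenance
#'   \code{"misregulated"} and a \code{direction} column.
#' @export
findMisregulatedRegions <- function(fc, layout, minGenes = 3L,
                                    minAbsLog2fc = 1.0, minMutants = 3L,
                                    sharedDirection = TRUE) {
  if (ncol(fc) < minMutants)
    stop("fewer mutant genotypes than minMutants")
  tab <- layout@genes
  i <- match(tab$gene_id, rownames(fc))
  nUp <- nDown <- integer(nrow(tab))
  has <- !is.na(i)
  nUp[has] <- rowSums(fc[i[has], , drop = FALSE] >= minAbsLog2fc)
  nDown[has] <- rowSums(fc[i[has], , drop = FALSE] <= -minAbsLog2fc)
  qual <- if (sharedDirection)
    list(up = nUp >= minMutants, down = nDown >= minMutants)
  else
    list(mixed = (nUp + nDown) >= minMutants)
  regions <- list()
  for (dir in names(qual)) {
    q <- qual[[dir]]
    for (ch in layout@chromosomes) {
      sel <- which(tab$chrom == ch)
      r <- rle(q[sel])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= minGenes
      for (j in which(keep)) {
        ids <- tab$gene_id[sel[starts[j]:ends[j]]]
        regions[[length(regions) + 1L]] <- list(members = ids, direction = dir)
      }
    }
  }
  set <- makeClusterSet(lapply(regions, `[[`, "members"), layout,
                        "misregulated", "MIS")
  df <- clusterTable(set)
  if (nrow(df)) {
    # makeClusterSet re-sorts; recover direction by member identity
    key <- vapply(regions, function(r) paste(r$members, collapse = ";"),
                  character(1))
    df$direction <- vapply(df$members, function(m)
      regions[[match(m, key)]]$direction, character(1))
  } else {
    df$direction <- character(0)
  }
  methods::new("GeneClusterSet", clusters = df)
}
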