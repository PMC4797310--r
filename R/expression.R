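#' Read a log2 expression matrix from TSV
#'
#' First column gives gene (or probe) IDs, remaining columns one sample each.
#' Values must already be on the log2 scale (e.g. RMA summaries); the reader
#' refuses matrices that look unlogged. Missing values are permitted and
#' handled pairwise downstream; infinite values are not.
#'
#' @param path TSV path (lines starting with '#' are ignored).
#' @return numeric matrix, rownames = gene IDs, colnames = sample IDs.
#' @export
readExpressionMatrix <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  validateExpressionMatrix(m)
  m
}

validateExpressionMatrix <- function(m) {
  if (is.null(rownames(m))) stop("expression matrix must have gene rownames")
  if (anyDuplicated(rownames(m))) stop("duplicated gene/probe IDs")
  if (any(is.infinite(m))) stop("expression values must be finite (or NA)")
  if (any(apply(is.na(m), 1, all)))
    stop("gene row(s) entirely missing")
  mx <- suppressWarnings(max(m, na.rm = TRUE))
  if (is.finite(mx) && mx > 30)
    stop("values exceed 30; input does not look log2-scaled ",
         "(apply log2 normalization upstream)")
  invisible(m)
}

#' Collapse probe-level rows to one row per gene
#'
#' Among probes mapping to the same gene, the row with the largest
#' interquartile range of its values is retained (ties broken by the
#' lexicographically smaller probe ID). Probes without a gene mapping are
#' dropped.
#'
#' @param raw probe-level matrix (rownames = probe IDs).
#' @param probeToGene named character vector (names = probe IDs, values =
#'   gene IDs) or a two-column data.frame (probe_id, gene_id).
#' @return gene-level matrix (rownames = gene IDs).
#' @export
collapseProbes <- function(raw, probeToGene) {
  if (is.data.frame(probeToGene))
    probeToGene <- stats::setNames(as.character(probeToGene[[2]]),
                                   as.character(probeToGene[[1]]))
  if (length(probeToGene) == 0L) stop("empty probe-to-gene mapping")
  if (anyDuplicated(names(probeToGene)))
    stop("a probe maps to more than one gene")
  keep <- rownames(raw) %in% names(probeToGene)
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no probes with a gene mapping")
  gene <- unname(probeToGene[rownames(raw)])
  iqr <- apply(raw, 1, stats::IQR, na.rm = TRUE)
  ord <- order(gene, -iqr, rownames(raw))
  pick <- ord[!duplicated(gene[ord])]
  out <- raw[pick, , drop = FALSE]
  rownames(out) <- gene[pick]
  out[order(rownames(out)), , drop = FALSE]
}

#' Banded Pearson correlations between neighbouring genes
#'
#' Computes the product-moment correlation for exactly the same-chromosome
#' gene pairs separated by 1..g ranks (the off-diagonal band of the full PCC
#' matrix) where both genes have expression rows. Rank separation is counted
#' over all annotated genes; genes without expression data occupy ranks but
#' form no pairs (set \code{expressedOnly = TRUE} to count separation over
#' the expression-covered subset instead). Zero-variance rows are excluded
#' with a message; with missing values, pairwise-complete correlations are
#' used and pairs sharing fewer than \code{minShared} samples are excluded.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param layout a \linkS4class{GenomeLayout}.
#' @param g integer window: maximum rank separation (>= 1).
#' @param expressedOnly count the g-gene window over expression-covered genes
#'   only, rather than over all annotated genes.
#' @param minShared minimum shared non-missing samples for a pair.
#' @return data.frame(gene_a, gene_b, distance, pcc) with attributes
#'   \code{universe} (genes eligible for edges) and \code{g}.
#' @export
bandedPCC <- function(expr, layout, g, expressedOnly = FALSE, minShared = 3L) {
  stopifnot(g >= 1L, ncol(expr) >= 3L)
  validateExpressionMatrix(expr)
  g <- as.integer(g)
  common <- intersect(geneIds(layout), rownames(expr))
  if (length(common) == 0L) stop("no layout genes with expression rows")

  hasNA <- anyNA(expr)
  if (!hasNA) {
    cm <- expr[common, , drop = FALSE] - rowMeans(expr[common, , drop = FALSE])
    ss <- sqrt(rowSums(cm^2))
    zeroVar <- ss == 0
    if (any(zeroVar))
      message(sum(zeroVar), " zero-variance gene row(s) excluded from correlation")
    scaled <- cm[!zeroVar, , drop = FALSE] / ss[!zeroVar]
    universe <- common[!zeroVar]
  } else {
    v <- apply(expr[common, , drop = FALSE], 1, stats::var, na.rm = TRUE)
    zeroVar <- !is.na(v) & v == 0
    if (any(zeroVar))
      message(sum(zeroVar), " zero-variance gene row(s) excluded from correlation")
    universe <- common[!zeroVar]
    scaled <- NULL
  }

  chromGenes <- chromGeneList(layout)
  resA <- resB <- character(0); resD <- integer(0); resP <- numeric(0)
  for (ch in names(chromGenes)) {
    ids <- chromGenes[[ch]]
    if (expressedOnly) ids <- ids[ids %in% universe]
    n <- length(ids)
    if (n < 2L) next
    inU <- ids %in% universe
    for (d in seq_len(min(g, n - 1L))) {
      i <- seq_len(n - d)
      ok <- inU[i] & inU[i + d]
      if (!any(ok)) next
      a <- ids[i[ok]]; b <- ids[i[ok] + d]
      if (!hasNA) {
        p <- rowSums(scaled[a, , drop = FALSE] * scaled[b, , drop = FALSE])
      } else {
        p <- vapply(seq_along(a), function(j) {
          x <- expr[a[j], ]; y <- expr[b[j], ]
          use <- !is.na(x) & !is.na(y)
          if (sum(use) < minShared) return(NA_real_)
          if (stats::sd(x[use]) == 0 || stats::sd(y[use]) == 0) return(NA_real_)
          stats::cor(x[use], y[use])
        }, numeric(1))
        drop <- is.na(p)
        a <- a[!drop]; b <- b[!drop]; p <- p[!drop]
      }
      resA <- c(resA, a); resB <- c(resB, b)
      resD <- c(resD, rep.int(d, length(a))); resP <- c(resP, p)
    }
  }
  out <- data.frame(gene_a = resA, gene_b = resB, distance = resD, pcc = resP,
                    stringsAsFactors = FALSE)
  attr(out, "universe") <- universe
  attr(out, "g") <- g
  out
}

# Internal fast path used by the gene-order shuffle null: banded correlations
# for an explicit per-chromosome gene ordering, from a pre-scaled matrix
# (rows centered, unit sum of squares). Returns only what edge construction
# needs: pair keys' indices and PCC values.
bandedPCCOrdered <- function(scaled, orderedIds, g) {
  resA <- resB <- character(0); resP <- numeric(0)
  inU <- lapply(orderedIds, function(ids) ids %in% rownames(scaled))
  for (k in seq_along(orderedIds)) {
    ids <- orderedIds[[k]]
    n <- length(ids)
    if (n < 2L) next
    u <- inU[[k]]
    for (d in seq_len(min(g, n - 1L))) {
      i <- seq_len(n - d)
      ok <- u[i] & u[i + d]
      if (!any(ok)) next
      a <- ids[i[ok]]; b <- ids[i[ok] + d]
      resA <- c(resA, a); resB <- c(resB, b)
      resP <- c(resP, rowSums(scaled[a, , drop = FALSE] * scaled[b, , drop = FALSE]))
    }
  }
  list(gene_a = resA, gene_b = resB, pcc = resP)
}

# Internal: center and unit-scale expression rows, dropping zero-variance rows.
scaleRows <- function(expr) {
  cm <- expr - rowMeans(expr)
  ss <- sqrt(rowSums(cm^2))
  cm[ss > 0, , drop = FALSE] / ss[ss > 0]
}
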