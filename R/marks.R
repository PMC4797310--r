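# Chromatin-mark runs: maximal stretches of contiguous marked genes and
# their Fisher-Yates permutation null, with an exact analytic expectation.

#' Construct a MarkTrack aligned to a layout
#'
#' @param markedIds gene IDs carrying the mark (e.g. H3K27me3-positive
#'   genes); IDs absent from the layout are dropped with a warning.
#' @param layout a \linkS4class{GenomeLayout}.
#' @return a \linkS4class{MarkTrack} (one boolean per layout gene, in
#'   layout order).
#' @export
MarkTrack <- function(markedIds, layout) {
  ids <- geneIds(layout)
  unknown <- setdiff(markedIds, ids)
  if (length(unknown))
    warning(length(unknown), " marked gene ID(s) absent from layout, dropped")
  methods::new("MarkTrack",
               marked = stats::setNames(ids %in% markedIds, ids))
}

#' @describeIn MarkTrack gene IDs carrying the mark.
#' @param x,object a \code{MarkTrack}.
#' @export
setMethod("markedGenes", "MarkTrack", function(x) names(x@marked)[x@marked])

#' @describeIn MarkTrack number of marked genes.
#' @export
setMethod("nMarked", "MarkTrack", function(x) sum(x@marked))

#' @describeIn MarkTrack total gene count.
#' @export
setMethod("nGenes", "MarkTrack", function(x) length(x@marked))

#' @describeIn MarkTrack show a summary.
#' @export
setMethod("show", "MarkTrack", function(object) {
  n <- length(object@marked); k <- sum(object@marked)
  cat(sprintf("MarkTrack: %d of %d genes marked (%.1f%%)\n",
              k, n, 100 * k / n))
})

#' Read marked genes from a gene-ID list or BED file
#'
#' A plain list has one gene ID per line ('#' comments allowed); a BED file
#' of marked gene bodies is resolved to gene IDs via its name column.
#'
#' @param path input path.
#' @param layout a \linkS4class{GenomeLayout}.
#' @return a \linkS4class{MarkTrack}.
#' @export
readMarkTrack <- function(path, layout) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- as.character(gr$name)
  } else {
    ids <- readLines(path)
    ids <- trimws(ids[!grepl("^#", ids) & nzchar(trimws(ids))])
  }
  MarkTrack(ids, layout)
}

# Internal: check track/layout alignment.
checkAligned <- function(track, layout) {
  if (!identical(names(track@marked), geneIds(layout)))
    stop("mark track is not aligned to the layout (gene IDs differ)")
}

#' Find maximal runs of contiguous marked genes
#'
#' A run is a maximal stretch of consecutive genes (in rank order, within
#' one chromosome) all carrying the mark; runs never cross chromosome
#' boundaries. Only runs of at least \code{minRun} genes are reported.
#'
#' @param track a \linkS4class{MarkTrack}.
#' @param layout the aligned \linkS4class{GenomeLayout}.
#' @param minRun minimum run length in genes (default 4, the mining
#'   criterion; 3 is the documented relaxation).
#' @return data.frame(run_id, chrom, start_rank, end_rank, length,
#'   start_bp, end_bp); \code{end_rank} is half-open.
#' @export
findMarkRuns <- function(track, layout, minRun = 4L) {
  stopifnot(minRun >= 1L)
  checkAligned(track, layout)
  tab <- layout@genes
  out <- list()
  for (ch in layout@chromosomes) {
    sel <- tab$chrom == ch
    m <- track@marked[tab$gene_id[sel]]
    r <- rle(as.vector(m))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minRun
    if (!any(keep)) next
    s <- starts[keep]; e <- ends[keep]
    out[[ch]] <- data.frame(
      chrom = ch,
      start_rank = s - 1L,
      end_rank = e,
      length = e - s + 1L,
      start_bp = tab$start[sel][s],
      end_bp = tab$end[sel][e],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(run_id = character(0), chrom = character(0),
                      start_rank = integer(0), end_rank = integer(0),
                      length = integer(0), start_bp = integer(0),
                      end_bp = integer(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(match(df$chrom, layout@chromosomes), df$start_rank), ]
  df <- cbind(run_id = sprintf("RUN%03d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Write mark runs as BED
#'
#' Chrom, 0-based bp start of the first gene, bp end of the last gene,
#' name = run ID, score = run length in genes.
#'
#' @param runs output of \code{\link{findMarkRuns}}.
#' @param path output path.
#' @export
writeMarkRunsBed <- function(runs, path) {
  bed <- data.frame(runs$chrom, runs$start_bp - 1L, runs$end_bp,
                    runs$run_id, runs$length)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fisher-Yates permutation null for mark-run counts
#'
#' Per replicate, the genome-wide mark vector is randomly permuted
#' (preserving the number of marked genes) and maximal runs of at least
#' \code{minRun} marked genes are recounted within chromosome boundaries.
#' The replicate draws the marked positions as a uniformly random k-subset,
#' which is exactly the distribution a Fisher-Yates shuffle of the binary
#' vector induces. With \code{stratifyByChromosome = TRUE} the shuffle is
#' instead performed independently within each chromosome, preserving
#' per-chromosome mark counts.
#'
#' @param track a \linkS4class{MarkTrack}.
#' @param layout the aligned \linkS4class{GenomeLayout}.
#' @param minRun minimum run length in genes.
#' @param nShuffles number of replicates (>= 2; 10,000 for the reference
#'   genome-scale null).
#' @param seed integer seed.
#' @param stratifyByChromosome shuffle within chromosomes instead of
#'   genome-wide.
#' @return a \linkS4class{ShuffleNull}.
#' @export
shuffleMarkNull <- function(track, layout, minRun = 4L, nShuffles = 10000L,
                            seed = 1L, stratifyByChromosome = FALSE) {
  stopifnot(nShuffles >= 2L)
  checkAligned(track, layout)
  observed <- nrow(findMarkRuns(track, layout, minRun))
  n <- length(track@marked)
  chromIdx <- match(layout@genes$chrom, layout@chromosomes)
  countFromPositions <- function(pos) {
    k <- length(pos)
    if (k == 0L) return(0L)
    pos <- sort.int(pos, method = "radix")
    if (k == 1L) return(as.integer(minRun <= 1L))
    newRun <- c(TRUE, pos[-1L] != pos[-k] + 1L |
                  chromIdx[pos[-1L]] != chromIdx[pos[-k]])
    sum(tabulate(cumsum(newRun)) >= minRun)
  }
  if (stratifyByChromosome) {
    perChromN <- tabulate(chromIdx)
    perChromK <- vapply(seq_along(perChromN), function(i)
      sum(track@marked[chromIdx == i]), integer(1))
    offsets <- cumsum(c(0L, perChromN[-length(perChromN)]))
    counts <- withSeed(seed, vapply(seq_len(nShuffles), function(i) {
      pos <- unlist(lapply(seq_along(perChromN), function(ci)
        offsets[ci] + sample.int(perChromN[ci], perChromK[ci])))
      countFromPositions(pos)
    }, integer(1)))
  } else {
    k <- sum(track@marked)
    counts <- withSeed(seed, vapply(seq_len(nShuffles), function(i)
      countFromPositions(sample.int(n, k)), integer(1)))
  }
  newShuffleNull(counts, observed, seed,
                 sprintf("runs of >=%d marked genes, mark shuffle", minRun))
}

#' Exact expected number of marked runs under random placement
#'
#' Expectation of the number of maximal runs of at least \code{r} marked
#' positions among all \eqn{C(n,k)} equally likely arrangements of \code{k}
#' marks in \code{n} positions on a single chromosome:
#' \deqn{E = [C(n-r, k-r) + (n-r) \, C(n-r-1, k-r)] / C(n, k)}
#' (the two terms count runs starting at position 1 and runs preceded by an
#' unmarked position). Computed with log-binomials, so it is exact to
#' floating-point precision at any n. Serves as the analytic oracle for
#' \code{\link{shuffleMarkNull}}.
#'
#' @param n number of positions (genes).
#' @param k number of marked positions, 0 <= k <= n.
#' @param r minimum run length, >= 1.
#' @return numeric expectation.
#' @export
expectedRunsExact <- function(n, k, r) {
  stopifnot(length(n) == 1L, length(k) == 1L, length(r) == 1L)
  if (k < 0 || k > n || r < 1 || n < 1) stop("require 0 <= k <= n and r >= 1")
  if (k < r) return(0)
  lc <- lchoose(n, k)
  first <- exp(lchoose(n - r, k - r) - lc)
  interior <- if (n - r >= 1) (n - r) * exp(lchoose(n - r - 1, k - r) - lc) else 0
  first + interior
}
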