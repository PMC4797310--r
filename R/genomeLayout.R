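#' Construct a GenomeLayout from a gene table
#'
#' Genes are sorted by (chromosome, start, gene ID) and assigned 0-based
#' ranks within each chromosome. Ranks are the pipeline's coordinate system:
#' two genes are "within g genes" when their ranks on the same chromosome
#' differ by at most g. Strand is recorded but ignored by all distance and
#' contiguity logic.
#'
#' @param genes data.frame with columns \code{chrom}, \code{gene_id},
#'   \code{start}, \code{end} and optionally \code{strand}.
#' @param chromOrder optional character vector fixing chromosome order;
#'   defaults to sorted unique chromosome names.
#' @param excludeOrganellar drop plastid/mitochondrial chromosomes
#'   (recognised by name: chrC/chrM/Pt/Mt and common synonyms).
#' @return a \linkS4class{GenomeLayout}.
#' @export
GenomeLayout <- function(genes, chromOrder = NULL, excludeOrganellar = TRUE) {
  stopifnot(is.data.frame(genes),
            all(c("chrom", "gene_id", "start", "end") %in% names(genes)))
  if (is.null(genes$strand)) genes$strand <- "+"
  genes$chrom <- as.character(genes$chrom)
  genes$gene_id <- as.character(genes$gene_id)
  genes$strand <- as.character(genes$strand)
  if (excludeOrganellar) {
    org <- tolower(genes$chrom) %in%
      c("chrc", "chrm", "pt", "mt", "chrpt", "chrmt",
        "plastid", "chloroplast", "mitochondria", "mito")
    genes <- genes[!org, , drop = FALSE]
  }
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene IDs: ",
         paste(utils::head(unique(genes$gene_id[duplicated(genes$gene_id)]), 3),
               collapse = ", "))
  if (is.null(chromOrder)) chromOrder <- sort(unique(genes$chrom))
  empty <- setdiff(chromOrder, unique(genes$chrom))
  if (length(empty)) {
    warning("dropping chromosome(s) with zero genes: ",
            paste(empty, collapse = ", "))
    chromOrder <- setdiff(chromOrder, empty)
  }
  if (nrow(genes) == 0L) stop("no genes left after filtering")
  genes <- genes[genes$chrom %in% chromOrder, , drop = FALSE]
  ord <- order(match(genes$chrom, chromOrder), genes$start, genes$gene_id)
  genes <- genes[ord, c("chrom", "gene_id", "start", "end", "strand")]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$rank <- unlist(lapply(split(seq_len(nrow(genes)), genes$chrom)[chromOrder],
                              function(i) seq_along(i) - 1L), use.names = FALSE)
  rownames(genes) <- NULL
  methods::new("GenomeLayout", genes = genes, chromosomes = chromOrder)
}

#' Load a GenomeLayout from GFF3 or BED annotation
#'
#' GFF3 records are filtered to \code{featureFilter} (default protein-coding
#' \code{"gene"} records) and identified by their \code{ID} attribute
#' (falling back to \code{Name}); BED input uses the name column. Both
#' encodings of the same genes yield identical layouts.
#'
#' @param file path to a GFF3 or BED file.
#' @param format \code{"auto"} (by extension), \code{"gff3"} or \code{"bed"}.
#' @param featureFilter GFF3 feature type to keep.
#' @param excludeOrganellar drop plastid/mitochondrial chromosomes.
#' @return a \linkS4class{GenomeLayout}.
#' @export
loadGenomeLayout <- function(file, format = c("auto", "gff3", "bed"),
                             featureFilter = "gene", excludeOrganellar = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", file, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(file, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == featureFilter]
    ids <- as.character(gr$ID)
    if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
    ids <- sub("^gene:", "", ids)
  } else {
    ids <- as.character(gr$name)
  }
  if (anyNA(ids)) stop("annotation records without a gene ID")
  genes <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      gene_id = ids,
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  GenomeLayout(genes, excludeOrganellar = excludeOrganellar)
}

#' @describeIn GenomeLayout gene IDs, in (chromosome, rank) order.
#' @param x,object a \code{GenomeLayout}.
#' @export
setMethod("geneIds", "GenomeLayout", function(x) x@genes$gene_id)

#' @describeIn GenomeLayout chromosome names, in layout order.
#' @export
setMethod("chromosomes", "GenomeLayout", function(x) x@chromosomes)

#' @describeIn GenomeLayout total gene count.
#' @export
setMethod("nGenes", "GenomeLayout", function(x) nrow(x@genes))

#' @describeIn GenomeLayout named integer ranks (0-based) for \code{ids}
#'   (default: all genes).
#' @param ids gene IDs to look up.
#' @export
setMethod("geneRanks", "GenomeLayout", function(x, ids = NULL) {
  if (is.null(ids)) return(stats::setNames(x@genes$rank, x@genes$gene_id))
  i <- match(ids, x@genes$gene_id)
  if (anyNA(i)) stop("unknown gene ID(s): ",
                     paste(utils::head(ids[is.na(i)], 3), collapse = ", "))
  stats::setNames(x@genes$rank[i], ids)
})

#' @describeIn GenomeLayout show a summary.
#' @export
setMethod("show", "GenomeLayout", function(object) {
  cat(sprintf("GenomeLayout: %d genes on %d chromosome(s) (%s)\n",
              nrow(object@genes), length(object@chromosomes),
              paste(utils::head(object@chromosomes, 5), collapse = ", ")))
})

#' Rank distance between two genes
#'
#' Absolute rank difference when both genes lie on the same chromosome,
#' \code{Inf} otherwise (distance across chromosomes is undefined).
#' Vectorised over pairs.
#'
#' @param layout a \linkS4class{GenomeLayout}.
#' @param a,b gene IDs (recycled to common length).
#' @return numeric vector of distances (\code{Inf} across chromosomes).
#' @export
geneDistance <- function(layout, a, b) {
  ia <- match(a, layout@genes$gene_id)
  ib <- match(b, layout@genes$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("unknown gene ID(s): ",
         paste(utils::head(c(a[is.na(ia)], b[is.na(ib)]), 3), collapse = ", "))
  d <- abs(layout@genes$rank[ia] - layout@genes$rank[ib])
  d[layout@genes$chrom[ia] != layout@genes$chrom[ib]] <- Inf
  as.numeric(d)
}

#' Serialize / restore a GenomeLayout as TSV
#'
#' Columns: chrom, rank, gene_id, start, end, strand. Reloading a written
#' layout round-trips exactly.
#'
#' @param layout a \linkS4class{GenomeLayout}.
#' @param path output (input) TSV path.
#' @return \code{writeGenomeLayout}: the path, invisibly.
#' @export
writeGenomeLayout <- function(layout, path) {
  g <- layout@genes[, c("chrom", "rank", "gene_id", "start", "end", "strand")]
  writeTsv(g, path, c(n_genes = nrow(g)))
}

#' @rdname writeGenomeLayout
#' @return \code{readGenomeLayout}: a \code{GenomeLayout}.
#' @export
readGenomeLayout <- function(path) {
  g <- readTsv(path)
  GenomeLayout(g[, c("chrom", "gene_id", "start", "end", "strand")],
               chromOrder = unique(g$chrom), excludeOrganellar = FALSE)
}

#' Coerce a GenomeLayout to GRanges
#'
#' @param layout a \linkS4class{GenomeLayout}.
#' @return a \code{GRanges} with mcols \code{gene_id} and \code{rank}.
#' @export
layoutAsGRanges <- function(layout) {
  g <- layout@genes
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand,
    gene_id = g$gene_id,
    rank = g$rank)
}

# Internal: per-chromosome gene IDs in rank order.
chromGeneList <- function(layout) {
  split(layout@genes$gene_id, factor(layout@genes$chrom, layout@chromosomes))
}
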