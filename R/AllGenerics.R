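#' @title Generics for mgcMiner containers
#' @name mgcMiner-generics
#' @description Accessor generics shared by the package's S4 containers.
#' @param x an mgcMiner object.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname mgcMiner-generics
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname mgcMiner-generics
#' @export
setGeneric("chromosomes", function(x, ...) standardGeneric("chromosomes"))

#' @rdname mgcMiner-generics
#' @export
setGeneric("nGenes", function(x, ...) standardGeneric("nGenes"))

#' @rdname mgcMiner-generics
#' @export
setGeneric("geneRanks", function(x, ...) standardGeneric("geneRanks"))

#' @rdname mgcMiner-generics
#' @export
setGeneric("nClusters", function(x, ...) standardGeneric("nClusters"))

#' @rdname mgcMiner-generics
#' @export
setGeneric("clusterMembers", function(x, ...) standardGeneric("clusterMembers"))

#' @rdname mgcMiner-generics
#' @export
setGeneric("markedGenes", function(x, ...) standardGeneric("markedGenes"))

#' @rdname mgcMiner-generics
#' @export
setGeneric("nMarked", function(x, ...) standardGeneric("nMarked"))

#' @rdname mgcMiner-generics
#' @export
setGeneric("duplicateTier", function(x, ...) standardGeneric("duplicateTier"))

#' @rdname mgcMiner-generics
#' @export
setGeneric("graphParams", function(x, ...) standardGeneric("graphParams"))
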