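# Accessor generics and show methods.

#' Accessors for landscape-family objects
#'
#' \code{genotypes} returns the genotype strings; \code{nodeScores} the
#' repression scores; \code{noiseTau} the per-genotype noise values;
#' \code{trueRepression} the ground-truth scores of a simulated landscape;
#' \code{peaks} the peak genotypes; \code{isPeak} the per-node peak flags;
#' \code{plateauIds} the per-node plateau membership; \code{relConnectivity}
#' the fraction of each genotype's \eqn{3L} possible neighbors present.
#'
#' @param x a \linkS4class{Landscape}, \linkS4class{GroundTruthLandscape} or
#'   \linkS4class{ScoreTable}.
#' @return A vector, one element per genotype (see the individual accessor).
#' @name accessors
#' @examples
#' ls <- buildNetwork(c(AA = 0, AT = 1, TT = 2, TA = 0.5),
#'                    genotypeSpace(2, context = NA))
#' genotypes(ls); nodeScores(ls); peaks(ls)
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("nodeScores", function(x) standardGeneric("nodeScores"))
#' @rdname accessors
#' @export
setGeneric("noiseTau", function(x) standardGeneric("noiseTau"))
#' @rdname accessors
#' @export
setGeneric("trueRepression", function(x) standardGeneric("trueRepression"))
#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setGeneric("isPeak", function(x) standardGeneric("isPeak"))
#' @rdname accessors
#' @export
setGeneric("plateauIds", function(x) standardGeneric("plateauIds"))
#' @rdname accessors
#' @export
setGeneric("relConnectivity", function(x) standardGeneric("relConnectivity"))

#' @rdname accessors
setMethod("genotypes", "Landscape", function(x) x@genotype)
#' @rdname accessors
setMethod("genotypes", "GroundTruthLandscape", function(x) x@genotype)
#' @rdname accessors
setMethod("genotypes", "ScoreTable", function(x) x$genotype)
#' @rdname accessors
setMethod("nodeScores", "Landscape", function(x)
    stats::setNames(x@score, x@genotype))
#' @rdname accessors
setMethod("noiseTau", "Landscape", function(x)
    stats::setNames(x@tau, x@genotype))
#' @rdname accessors
setMethod("trueRepression", "GroundTruthLandscape", function(x)
    stats::setNames(x@trueRepression, x@genotype))
#' @rdname accessors
setMethod("peaks", "Landscape", function(x) x@genotype[x@isPeak])
#' @rdname accessors
setMethod("isPeak", "Landscape", function(x)
    stats::setNames(x@isPeak, x@genotype))
#' @rdname accessors
setMethod("plateauIds", "Landscape", function(x)
    stats::setNames(x@plateauId, x@genotype))
#' @rdname accessors
setMethod("relConnectivity", "Landscape", function(x)
    stats::setNames(x@relConnectivity, x@genotype))

setMethod("show", "GenotypeSpace", function(object) {
    cat("GenotypeSpace:", object@length, "variable positions over {A,C,G,T}",
        sprintf("(%s genotypes)\n", format(4^object@length, big.mark = ",")))
    if (!is.na(object@context))
        cat("  context:", object@context, "\n")
})

setMethod("show", "GroundTruthLandscape", function(object) {
    cat(sprintf("GroundTruthLandscape (%s model): %d genotypes, L = %d, seed = %d\n",
        object@modelKind, length(object@genotype), object@space@length,
        object@seed))
    cat(sprintf("  true repression range: [%.3g, %.3g]\n",
        min(object@trueRepression), max(object@trueRepression)))
})

setMethod("show", "Landscape", function(object) {
    n <- length(object@genotype)
    cat(sprintf("Landscape: %d genotypes, %d edges, L = %d\n",
        n, nrow(object@edges), object@space@length))
    cat(sprintf("  peaks: %d (%d plateaus)", sum(object@isPeak),
        length(unique(stats::na.omit(object@plateauId)))))
    if (!is.na(object@noiseScale))
        cat(sprintf("  [noise-aware, scale = %g]", object@noiseScale))
    cat("\n")
    if (n) cat(sprintf("  score range: [%.3g, %.3g]\n",
        min(object@score), max(object@score)))
})

setMethod("show", "SortSeqConfig", function(object) {
    cat(sprintf(
        "SortSeqConfig: %d bins, %d replicates, %d cells/genotype, seed = %d\n",
        object@nBins, object@nReplicates, object@cellsPerGenotype,
        object@seed))
    cat(sprintf("  noise (log2 s.d.): cell %.2f, replicate %.2f; map: %.3g a.u. * 2^(-%g S), floor %.3g\n",
        object@cellNoiseSd, object@replicateNoiseSd, object@fluorMax,
        object@logSlope, object@fluorFloor))
})

setMethod("show", "WalkResult", function(object) {
    cat(sprintf("WalkResult (%s): %s -> %s in %d steps%s\n",
        object@mode, object@start, object@endpoint, object@steps,
        if (isTRUE(object@endpointIsHighPeak)) " [high peak]"
        else if (isTRUE(object@endpointIsPeak)) " [peak]" else ""))
})
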