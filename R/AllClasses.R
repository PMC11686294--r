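#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

#' GenotypeSpace: the combinatorial space of binding-site variants
#'
#' A \code{GenotypeSpace} defines the Hamming graph underlying a binding-site
#' library: the number of randomised positions \code{L}, the nucleotide
#' alphabet, and the fixed flanking context into which the variable positions
#' are embedded. The default context is the 19-nt \emph{tetO2} operator
#' scaffold \code{TCCCNNNNAGTNNNNGAGA} with eight randomised positions.
#'
#' @slot length integer, number of variable positions L.
#' @slot alphabet character, the allele set (always \code{A,C,G,T} here).
#' @slot context character, fixed flanking sequence with \code{N} at each
#'   variable position; \code{NA} for a bare (context-free) space.
#'
#' @exportClass GenotypeSpace
setClass("GenotypeSpace",
    representation(length = "integer", alphabet = "character",
                   context = "character"))

setValidity("GenotypeSpace", function(object) {
    msg <- NULL
    if (length(object@length) != 1L || is.na(object@length) || object@length < 1L)
        msg <- c(msg, "'length' must be a single positive integer")
    if (!identical(object@alphabet, DNA_ALPHABET))
        msg <- c(msg, "alphabet must be A,C,G,T")
    if (!is.na(object@context)) {
        nN <- sum(strsplit(object@context, "")[[1]] == "N")
        if (nN != object@length)
            msg <- c(msg, sprintf(
                "context has %d 'N' placeholders but length is %d",
                nN, object@length))
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeSpace
#'
#' @param length number of variable positions (default 8).
#' @param context fixed context sequence containing one \code{N} per variable
#'   position, or \code{NA} for no context. The default is the \emph{tetO2}
#'   scaffold used for TetR binding-site libraries.
#' @return A \linkS4class{GenotypeSpace}.
#' @examples
#' sp <- genotypeSpace(8)
#' sp
#' genotypeSpace(2, context = NA)
#' @export
genotypeSpace <- function(length = 8L,
                          context = if (length == 8L) "TCCCNNNNAGTNNNNGAGA" else NA_character_) {
    new("GenotypeSpace", length = as.integer(length),
        alphabet = DNA_ALPHABET, context = as.character(context))
}

#' GroundTruthLandscape: a simulated genotype-to-repression map
#'
#' Holds a ground-truth repression value for every genotype of a
#' \linkS4class{GenotypeSpace}, generated by one of the statistical landscape
#' models (additive, NK, or House-of-Cards). Used as the known truth against
#' which the sort-seq scoring pipeline is validated.
#'
#' @slot space the \linkS4class{GenotypeSpace}.
#' @slot genotype character vector of all genotypes (variable positions only).
#' @slot trueRepression numeric, ground-truth repression per genotype.
#' @slot modelKind one of \code{"additive"}, \code{"NK"}, \code{"HoC"}.
#' @slot modelParams list of model parameters (site weights, K and component
#'   tables, or score-distribution parameters).
#' @slot seed integer seed used to generate the landscape.
#'
#' @exportClass GroundTruthLandscape
setClass("GroundTruthLandscape",
    representation(space = "GenotypeSpace", genotype = "character",
                   trueRepression = "numeric", modelKind = "character",
                   modelParams = "list", seed = "integer"))

setValidity("GroundTruthLandscape", function(object) {
    msg <- NULL
    if (length(object@genotype) != length(object@trueRepression))
        msg <- c(msg, "genotype and trueRepression lengths differ")
    if (any(object@trueRepression < 0))
        msg <- c(msg, "trueRepression must be non-negative")
    if (!object@modelKind %in% c("additive", "NK", "HoC"))
        msg <- c(msg, "modelKind must be additive, NK or HoC")
    if (length(object@genotype) &&
        !all(nchar(object@genotype) == object@space@length))
        msg <- c(msg, "genotype length does not match the space")
    if (is.null(msg)) TRUE else msg
})

#' SortSeqConfig: forward-model parameters for simulated sort-seq
#'
#' Parameters of the simulated sorting experiment: the repression-to-
#' fluorescence map, single-cell and between-replicate log-normal noise,
#' gating, and sequencing depth. Defaults emulate a 13-bin FACS sort with
#' log2-equidistant interior gates, an autofluorescence floor, and a median
#' per-genotype depth of about 100 reads so that the downstream 30-read
#' filter is comfortably exercised.
#'
#' @slot nBins integer number of fluorescence gates (default 13).
#' @slot gateBoundaries numeric vector of nBins-1 increasing boundaries, or
#'   empty to derive them from the simulated population (bin-1 upper bound at
#'   the autofluorescence median, bin-nBins lower bound at the population 95th
#'   percentile, interior boundaries log2-equidistant).
#' @slot cellsPerGenotype integer cells sorted per genotype per replicate.
#' @slot readsTotal numeric total reads per replicate (NA: 100 per genotype).
#' @slot nReplicates integer number of replicates (default 3).
#' @slot cellNoiseSd single-cell fluorescence s.d., log2 units.
#' @slot replicateNoiseSd between-replicate per-genotype s.d., log2 units.
#' @slot fluorMax expected fluorescence of a fully unrepressed genotype (a.u.).
#' @slot fluorFloor autofluorescence median (a.u.); fluorescence saturates here.
#' @slot logSlope log2-fluorescence decrease per unit of repression.
#' @slot dropoutRate fraction of genotypes randomly lost per replicate
#'   (default 0: no post-sort diversity loss is modelled).
#' @slot seed integer seed.
#'
#' @exportClass SortSeqConfig
setClass("SortSeqConfig",
    representation(nBins = "integer", gateBoundaries = "numeric",
                   cellsPerGenotype = "integer", readsTotal = "numeric",
                   nReplicates = "integer", cellNoiseSd = "numeric",
                   replicateNoiseSd = "numeric", fluorMax = "numeric",
                   fluorFloor = "numeric", logSlope = "numeric",
                   dropoutRate = "numeric", seed = "integer"))

setValidity("SortSeqConfig", function(object) {
    msg <- NULL
    if (object@nBins < 2L) msg <- c(msg, "need at least 2 bins")
    if (length(object@gateBoundaries) &&
        (length(object@gateBoundaries) != object@nBins - 1L ||
         any(diff(object@gateBoundaries) <= 0)))
        msg <- c(msg, "gateBoundaries must be nBins-1 strictly increasing values")
    if (!is.na(object@readsTotal) && object@readsTotal <= 0)
        msg <- c(msg, "readsTotal must be positive")
    if (object@cellNoiseSd < 0 || object@replicateNoiseSd < 0)
        msg <- c(msg, "noise s.d. must be non-negative")
    if (object@logSlope <= 0)
        msg <- c(msg, "logSlope must be positive (repression must decrease fluorescence)")
    if (object@fluorMax <= object@fluorFloor)
        msg <- c(msg, "fluorMax must exceed fluorFloor")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
        msg <- c(msg, "dropoutRate must be in [0,1)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SortSeqConfig
#'
#' @param nBins,gateBoundaries,cellsPerGenotype,readsTotal,nReplicates
#'   see \linkS4class{SortSeqConfig}.
#' @param cellNoiseSd,replicateNoiseSd,fluorMax,fluorFloor,logSlope,dropoutRate,seed
#'   see \linkS4class{SortSeqConfig}.
#' @return A \linkS4class{SortSeqConfig}.
#' @examples
#' cfg <- sortSeqConfig(seed = 1)
#' @export
sortSeqConfig <- function(nBins = 13L, gateBoundaries = numeric(0),
                          cellsPerGenotype = 100L, readsTotal = NA_real_,
                          nReplicates = 3L, cellNoiseSd = 0.8,
                          replicateNoiseSd = 0.9, fluorMax = 1e5,
                          fluorFloor = 100, logSlope = 8,
                          dropoutRate = 0, seed = 1L) {
    new("SortSeqConfig", nBins = as.integer(nBins),
        gateBoundaries = as.numeric(gateBoundaries),
        cellsPerGenotype = as.integer(cellsPerGenotype),
        readsTotal = as.numeric(readsTotal),
        nReplicates = as.integer(nReplicates),
        cellNoiseSd = as.numeric(cellNoiseSd),
        replicateNoiseSd = as.numeric(replicateNoiseSd),
        fluorMax = as.numeric(fluorMax), fluorFloor = as.numeric(fluorFloor),
        logSlope = as.numeric(logSlope), dropoutRate = as.numeric(dropoutRate),
        seed = as.integer(seed))
}

#' BinCountTable: genotype x fluorescence-bin read counts per replicate
#'
#' A \linkS4class{SummarizedExperiment} with genotypes as rows, bins as
#' columns (\code{colData(x)$bin} giving the 1-based bin weight), and one
#' integer assay per replicate, named \code{rep1}, \code{rep2}, ...
#' Metadata holds the \linkS4class{GenotypeSpace} and provenance.
#'
#' @exportClass BinCountTable
setClass("BinCountTable", contains = "SummarizedExperiment")

setValidity("BinCountTable", function(object) {
    msg <- NULL
    if (length(SummarizedExperiment::assays(object)) < 1L)
        msg <- c(msg, "at least one replicate assay required")
    for (a in as.list(SummarizedExperiment::assays(object))) {
        if (any(a < 0)) { msg <- c(msg, "counts must be non-negative"); break }
        if (any(a != round(a))) { msg <- c(msg, "counts must be integers"); break }
    }
    if (is.null(SummarizedExperiment::colData(object)$bin))
        msg <- c(msg, "colData must have a 'bin' column of bin weights")
    if (is.null(rownames(object)))
        msg <- c(msg, "rownames (genotypes) required")
    if (is.null(msg)) TRUE else msg
})

#' ScoreTable: filtered, replicate-combined repression scores
#'
#' An \linkS4class{DataFrame} subclass with one row per genotype surviving the
#' replicate filters. Columns: \code{genotype}; per-replicate expression
#' \code{e_rep*}, repression \code{r_rep*} and read totals \code{reads_rep*};
#' the replicate-mean raw repression \code{meanR}; its coefficient of
#' variation \code{cv}; the wild-type-normalised score \code{S}; and the noise
#' estimate \code{tau} (s.d. of normalised per-replicate scores). \code{S} and
#' \code{tau} are \code{NA} until \code{\link{normalizeByWildtype}} is applied.
#'
#' @exportClass ScoreTable
setClass("ScoreTable", contains = "DFrame")

#' Landscape: a score-annotated genotype network
#'
#' The central object of the package: observed genotypes with repression
#' scores, the undirected Hamming-distance-1 adjacency among them, directed
#' uphill edges (optionally noise-aware), and derived peak/plateau labels.
#'
#' Edge orientation is canonical uphill (low score to high score). Without a
#' noise model an edge is \emph{neutral} only on an exact score tie (optional
#' epsilon). With a noise model, an edge is oriented only when the endpoints
#' are distinguishable given their per-genotype noise \code{tau}
#' (see \code{\link{applyNoiseModel}}); indistinguishable pairs are neutral.
#'
#' A node is a \emph{peak} (local maximum) iff it has no distinguishably
#' higher neighbor; a \emph{plateau} is a connected set of peaks joined by
#' neutral edges.
#'
#' @slot space the \linkS4class{GenotypeSpace}.
#' @slot genotype character vector of node genotypes.
#' @slot score numeric repression score per node.
#' @slot tau numeric per-node noise (zero when no noise model).
#' @slot edges integer matrix (m x 2) of undirected edges (node indices,
#'   first column < second column).
#' @slot edgeState integer per edge: 1 = uphill from col1 to col2,
#'   2 = uphill from col2 to col1, 0 = neutral (tie / indistinguishable).
#' @slot isPeak logical per node.
#' @slot plateauId integer plateau membership per node (NA for non-peaks).
#' @slot relConnectivity numeric per node: observed neighbors / (3 L).
#' @slot noiseScale numeric; NA when no noise model is active.
#' @slot provenance list (filters, seeds, config hash).
#'
#' @exportClass Landscape
setClass("Landscape",
    representation(space = "GenotypeSpace", genotype = "character",
                   score = "numeric", tau = "numeric", edges = "matrix",
                   edgeState = "integer", isPeak = "logical",
                   plateauId = "integer", relConnectivity = "numeric",
                   noiseScale = "numeric", provenance = "list"))

setValidity("Landscape", function(object) {
    n <- length(object@genotype)
    msg <- NULL
    if (anyDuplicated(object@genotype))
        msg <- c(msg, "duplicate genotypes")
    for (s in c("score", "tau", "isPeak", "plateauId", "relConnectivity"))
        if (length(slot(object, s)) != n)
            msg <- c(msg, sprintf("slot '%s' length != number of nodes", s))
    if (nrow(object@edges) != length(object@edgeState))
        msg <- c(msg, "edgeState length != number of edges")
    if (nrow(object@edges) && max(object@edges) > n)
        msg <- c(msg, "edge index out of range")
    if (any(object@tau < 0)) msg <- c(msg, "tau must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' WalkResult: one adaptive walk on a landscape
#'
#' @slot start starting genotype.
#' @slot trajectory character vector of successively fixed genotypes
#'   (starts with \code{start}).
#' @slot steps integer number of fixed mutational steps.
#' @slot endpoint final genotype.
#' @slot endpointIsPeak,endpointIsHighPeak logical.
#' @slot selectionCoefficients numeric score difference of each fixed step.
#' @slot visitedPeaks character, every peak genotype visited (relevant for
#'   Kimura walks, which may leave peaks again by drift).
#' @slot mode one of \code{"greedy"}, \code{"uniform"}, \code{"kimura"}.
#'
#' @exportClass WalkResult
setClass("WalkResult",
    representation(start = "character", trajectory = "character",
                   steps = "integer", endpoint = "character",
                   endpointIsPeak = "logical", endpointIsHighPeak = "logical",
                   selectionCoefficients = "numeric",
                   visitedPeaks = "character", mode = "character"))

setValidity("WalkResult", function(object) {
    msg <- NULL
    if (length(object@trajectory) < 1L)
        msg <- c(msg, "trajectory must contain at least the start")
    if (object@trajectory[1L] != object@start)
        msg <- c(msg, "trajectory must begin at start")
    if (object@endpoint != object@trajectory[length(object@trajectory)])
        msg <- c(msg, "endpoint must be the last trajectory member")
    if (object@steps != length(object@trajectory) - 1L)
        msg <- c(msg, "steps must equal trajectory length - 1")
    if (is.null(msg)) TRUE else msg
})
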