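# Ground-truth landscape models. These are the oracles against which the
# scoring and topography code is validated: an additive model with distinct
# positive best-allele margins has exactly one local maximum; a House-of-Cards
# model has i.i.d. scores and an expected peak count of 4^L/(3L+1) on the
# complete 4-allele Hamming graph; the NK model interpolates between the two.

#' Additive ground-truth landscape
#'
#' Scores each genotype as the sum of per-position, per-allele weights. With
#' strictly distinct positive best-allele margins the landscape is smooth:
#' it has exactly one local maximum (the genotype taking the best allele at
#' every position) and every shortest path towards it is accessible.
#'
#' @param space a \linkS4class{GenotypeSpace}.
#' @param siteWeights a 4 x L numeric matrix (rows named A,C,G,T) of
#'   per-position allele weights, or \code{NULL} to draw random weights.
#' @param seed integer seed (used only when weights are drawn).
#' @return A \linkS4class{GroundTruthLandscape}.
#' @examples
#' w <- matrix(0:3, 4, 1, dimnames = list(c("A","C","G","T"), NULL))
#' tr <- makeAdditiveLandscape(genotypeSpace(1, context = NA), w)
#' trueRepression(tr)
#' @export
makeAdditiveLandscape <- function(space, siteWeights = NULL, seed = 1L) {
    L <- space@length
    if (is.null(siteWeights))
        siteWeights <- .withSeed(seed, matrix(stats::runif(4L * L), 4L, L,
                                 dimnames = list(DNA_ALPHABET, NULL)))
    if (!is.matrix(siteWeights) || nrow(siteWeights) != 4L ||
        ncol(siteWeights) != L || anyNA(siteWeights))
        stop("siteWeights must be a complete 4 x L matrix (rows A,C,G,T)")
    if (!is.null(rownames(siteWeights)) &&
        !identical(rownames(siteWeights), DNA_ALPHABET))
        siteWeights <- siteWeights[DNA_ALPHABET, , drop = FALSE]
    g <- enumerateGenotypes(space)
    m <- .alleleIndexMatrix(g, L)
    sc <- numeric(length(g))
    for (p in seq_len(L))
        sc <- sc + siteWeights[m[, p] + 1L, p]
    sc <- sc - min(sc)   # repression is non-negative by convention
    new("GroundTruthLandscape", space = space, genotype = g,
        trueRepression = sc, modelKind = "additive",
        modelParams = list(siteWeights = siteWeights),
        seed = as.integer(seed))
}

#' House-of-Cards ground-truth landscape
#'
#' Draws an i.i.d. score for every genotype, so that neighboring genotypes
#' have uncorrelated repression values: the maximally rugged null. On the
#' complete 4-allele Hamming graph the expected number of local maxima is
#' \eqn{4^L/(3L+1)} (each genotype is a peak iff it is the largest of itself
#' and its 3L neighbors).
#'
#' @param space a \linkS4class{GenotypeSpace}.
#' @param distribution \code{"uniform"} or \code{"exponential"} (both
#'   continuous, so score ties have probability zero).
#' @param seed integer seed; the same seed reproduces scores bit-identically.
#' @return A \linkS4class{GroundTruthLandscape}.
#' @examples
#' tr <- makeHoCLandscape(genotypeSpace(3, context = NA), seed = 7)
#' @export
makeHoCLandscape <- function(space, distribution = c("uniform", "exponential"),
                             seed = 1L) {
    distribution <- match.arg(distribution)
    g <- enumerateGenotypes(space)
    sc <- .withSeed(seed, switch(distribution,
                 uniform = stats::runif(length(g)),
                 exponential = stats::rexp(length(g))))
    new("GroundTruthLandscape", space = space, genotype = g,
        trueRepression = sc, modelKind = "HoC",
        modelParams = list(distribution = distribution),
        seed = as.integer(seed))
}

#' NK ground-truth landscape (tunable ruggedness)
#'
#' Kauffman-style NK model over a 4-letter alphabet: the score of a genotype
#' is the mean of L per-site component functions, each depending on the
#' site's allele and the alleles of its K right-hand neighbors (circular).
#' \code{K = 0} reduces to an additive landscape; \code{K = L - 1} makes
#' every component depend on the whole genotype and is statistically
#' indistinguishable from House-of-Cards.
#'
#' @param space a \linkS4class{GenotypeSpace}.
#' @param K integer interaction order, \code{0 <= K <= L-1}.
#' @param seed integer seed; component tables are reproducible.
#' @return A \linkS4class{GroundTruthLandscape}.
#' @examples
#' tr <- makeNKLandscape(genotypeSpace(4, context = NA), K = 1, seed = 3)
#' @export
makeNKLandscape <- function(space, K, seed = 1L) {
    L <- space@length
    K <- as.integer(K)
    if (K < 0L || K > L - 1L)
        stop("K must satisfy 0 <= K <= L-1")
    g <- enumerateGenotypes(space)
    m <- .alleleIndexMatrix(g, L)
    tables <- .withSeed(seed,
        lapply(seq_len(L), function(p) stats::runif(4^(K + 1L))))
    sc <- numeric(length(g))
    for (p in seq_len(L)) {
        sites <- ((p - 1L + 0:K) %% L) + 1L
        idx <- numeric(length(g))
        for (k in seq_along(sites))
            idx <- idx + m[, sites[k]] * 4^(k - 1)
        sc <- sc + tables[[p]][idx + 1L]
    }
    new("GroundTruthLandscape", space = space, genotype = g,
        trueRepression = sc / L, modelKind = "NK",
        modelParams = list(K = K, componentTables = tables),
        seed = as.integer(seed))
}
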