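# Landscape construction and annotation: Hamming adjacency, canonical uphill
# edge orientation (noise-free or noise-aware), peaks, plateaus, the giant
# component, and the shuffled null.

# Core annotator. Orients every undirected edge:
#   state 1: uphill from col1 to col2
#   state 2: uphill from col2 to col1
#   state 0: neutral (exact tie within epsilon; or, with a noise model,
#            scores indistinguishable given tau)
# A node is a peak iff no edge points distinguishably uphill away from it.
# Plateaus are connected components of peaks joined by neutral edges.
.makeLandscape <- function(space, genotype, score, tau = NULL,
                           noiseScale = NA_real_, epsilon = 0,
                           provenance = list(), edges = NULL) {
    n <- length(genotype)
    if (is.null(tau)) tau <- numeric(n)
    if (anyNA(score)) stop("scores contain NA")
    if (anyDuplicated(genotype)) stop("duplicate genotypes")
    if (is.null(edges)) edges <- .hammingEdges(genotype, space@length)
    e1 <- edges[, 1L]; e2 <- edges[, 2L]
    if (is.na(noiseScale)) {
        d <- score[e2] - score[e1]
        state <- ifelse(abs(d) <= epsilon, 0L, ifelse(d > 0, 1L, 2L))
    } else {
        if (anyNA(tau)) stop("tau missing for some genotypes")
        t1 <- tau[e1] * noiseScale; t2 <- tau[e2] * noiseScale
        up <- score[e2] - t2 > score[e1] + t1   # col2 distinguishably higher
        dn <- score[e1] - t1 > score[e2] + t2
        state <- ifelse(up, 1L, ifelse(dn, 2L, 0L))
    }
    state <- as.integer(state)
    isPeak <- rep(TRUE, n)
    isPeak[e1[state == 1L]] <- FALSE
    isPeak[e2[state == 2L]] <- FALSE
    plateauId <- rep(NA_integer_, n)
    pk <- which(isPeak)
    if (length(pk)) {
        sel <- state == 0L & isPeak[e1] & isPeak[e2]
        pidx <- match(seq_len(n), pk)
        gpk <- igraph::graph_from_edgelist(
            cbind(pidx[e1[sel]], pidx[e2[sel]]), directed = FALSE)
        gpk <- igraph::add_vertices(gpk,
            max(0L, length(pk) - igraph::vcount(gpk)))
        plateauId[pk] <- as.integer(
            igraph::components(gpk)$membership[seq_along(pk)])
    }
    deg <- tabulate(c(e1, e2), nbins = n)
    new("Landscape", space = space, genotype = genotype,
        score = as.numeric(score), tau = as.numeric(tau),
        edges = edges, edgeState = state, isPeak = isPeak,
        plateauId = plateauId,
        relConnectivity = deg / (3 * space@length),
        noiseScale = as.numeric(noiseScale),
        provenance = c(provenance, list(epsilon = epsilon)))
}

#' Build a score-annotated genotype network
#'
#' Connects every pair of observed genotypes differing at exactly one
#' variable position, annotates each node with its repression score (and
#' noise \code{tau} where available), orients uphill edges from lower to
#' higher score, and labels peaks and plateaus.
#'
#' @param scores a \linkS4class{ScoreTable} (normalised scores \code{S} are
#'   used; run \code{\link{normalizeByWildtype}} first), a
#'   \linkS4class{GroundTruthLandscape}, or a named numeric vector of scores
#'   keyed by genotype.
#' @param space a \linkS4class{GenotypeSpace}; inferred when \code{scores}
#'   carries one.
#' @param epsilon score-tie tolerance for neutral edges (default 0: exact
#'   floating-point equality defines plateau membership).
#' @return A \linkS4class{Landscape} (noise-free orientation; see
#'   \code{\link{applyNoiseModel}} for the noise-aware variant).
#' @examples
#' ls <- buildNetwork(c(AA = 0, AT = 1, TT = 2, TA = 0.5),
#'                    genotypeSpace(2, context = NA))
#' peaks(ls)
#' @export
buildNetwork <- function(scores, space = NULL, epsilon = 0) {
    if (is(scores, "ScoreTable")) {
        if (is.null(space)) space <- metadata(scores)$space
        s <- scores$S
        if (all(is.na(s))) s <- scores$meanR
        tau <- scores$tau
        if (all(is.na(tau))) tau <- numeric(nrow(scores))
        return(.makeLandscape(space, scores$genotype, s, tau,
                              epsilon = epsilon,
                              provenance = list(source = "ScoreTable",
                                  filters = metadata(scores)[c("minReads", "maxCV", "perBin")])))
    }
    if (is(scores, "GroundTruthLandscape")) {
        if (is.null(space)) space <- scores@space
        return(.makeLandscape(space, scores@genotype, scores@trueRepression,
                              epsilon = epsilon,
                              provenance = list(source = scores@modelKind,
                                                seed = scores@seed)))
    }
    if (is.numeric(scores) && !is.null(names(scores))) {
        if (is.null(space)) stop("supply a GenotypeSpace for a plain score vector")
        return(.makeLandscape(space, names(scores), unname(scores),
                              epsilon = epsilon,
                              provenance = list(source = "vector")))
    }
    stop("unsupported 'scores' input")
}

#' Extract the giant component of a landscape
#'
#' Returns the landscape restricted to its largest connected subgraph.
#' Size ties are broken deterministically in favour of the component whose
#' lexicographically smallest genotype is smallest.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @return A \linkS4class{Landscape} on the giant component (re-annotated).
#' @export
giantComponent <- function(landscape) {
    n <- length(landscape@genotype)
    if (n == 0L) stop("empty landscape")
    g <- igraph::graph_from_edgelist(landscape@edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)
    best <- which(comp$csize == max(comp$csize))
    if (length(best) > 1L) {
        mins <- vapply(best, function(cid)
            min(landscape@genotype[comp$membership == cid]), character(1))
        best <- best[order(mins)[1L]]
    }
    keep <- which(comp$membership == best)
    subsetLandscape(landscape, keep)
}

#' Restrict a landscape to a subset of its nodes
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param i integer indices or genotype strings to keep.
#' @return A re-annotated \linkS4class{Landscape} on the kept nodes.
#' @export
subsetLandscape <- function(landscape, i) {
    if (is.character(i)) i <- match(i, landscape@genotype)
    if (anyNA(i)) stop("unknown genotypes in subset")
    .makeLandscape(landscape@space, landscape@genotype[i],
                   landscape@score[i], landscape@tau[i],
                   noiseScale = landscape@noiseScale,
                   epsilon = landscape@provenance$epsilon %||% 0,
                   provenance = landscape@provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Peaks and plateaus of a landscape
#'
#' A peak is a genotype none of whose neighbors conveys distinguishably
#' higher repression; connected equal-score (or, with a noise model,
#' indistinguishable) peaks together form a plateau, and each plateau member
#' still counts individually as a peak. Peak breadth is the number of peaks
#' per plateau.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @return List with \code{peaks} (character), \code{plateaus} (list of
#'   character vectors), \code{peakCount}, \code{plateauCount},
#'   \code{meanBreadth}, and \code{strictPeakCount} (genotypes distinguishably
#'   above \emph{all} their neighbors; equal to \code{peakCount} on tie-free
#'   noise-free landscapes).
#' @export
findPeaks <- function(landscape) {
    pk <- landscape@genotype[landscape@isPeak]
    pid <- landscape@plateauId[landscape@isPeak]
    plateaus <- split(pk, pid)
    names(plateaus) <- NULL
    e1 <- landscape@edges[, 1L]; e2 <- landscape@edges[, 2L]
    st <- landscape@edgeState
    strict <- rep(TRUE, length(landscape@genotype))
    strict[e1[st != 2L]] <- FALSE   # edge not distinguishably downhill from e1
    strict[e2[st != 1L]] <- FALSE
    strict[tabulate(c(e1, e2), length(strict)) == 0L] <- TRUE  # isolated nodes
    list(peaks = pk, plateaus = plateaus,
         peakCount = length(pk), plateauCount = length(plateaus),
         meanBreadth = if (length(plateaus)) mean(lengths(plateaus)) else 0,
         strictPeakCount = sum(strict))
}

#' Re-orient a landscape under a per-genotype noise model
#'
#' Re-assigns edge directions using per-genotype noise values: for adjacent
#' genotypes A and B with scores \eqn{S_A, S_B} and noise \eqn{\tau_A,
#' \tau_B} (each multiplied by \code{scale}), A is considered distinguishably
#' higher than B only if \eqn{S_A > S_B + \tau_B} and
#' \eqn{S_A - \tau_A > S_B + \tau_B}. Distinguishable pairs get a single
#' uphill edge; indistinguishable pairs become neutral (traversable in both
#' directions). Peaks and plateaus are recomputed: a node is a local maximum
#' iff it has no distinguishably higher neighbor, so raising \code{scale}
#' can only merge peaks into broader plateaus.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param tau optional per-genotype noise vector (defaults to the landscape's
#'   stored \code{tau}).
#' @param scale noise scale factor (e.g. 1, 1.1, 1.25, 1.5); \code{scale = 0}
#'   reproduces the noise-free landscape.
#' @return A re-annotated \linkS4class{Landscape} with
#'   \code{noiseScale = scale}.
#' @export
applyNoiseModel <- function(landscape, tau = NULL, scale = 1) {
    if (is.null(tau)) tau <- landscape@tau
    if (length(tau) != length(landscape@genotype) || anyNA(tau))
        stop("tau must be available for every node")
    if (scale < 0) stop("scale must be non-negative")
    .makeLandscape(landscape@space, landscape@genotype, landscape@score,
                   tau, noiseScale = scale,
                   epsilon = landscape@provenance$epsilon %||% 0,
                   provenance = landscape@provenance,
                   edges = landscape@edges)
}

#' Peak counts of randomly shuffled landscapes
#'
#' Permutes the repression scores uniformly at random over the genotypes
#' (preserving the score distribution but destroying its spatial
#' correlation), recomputes the number of peaks, and repeats. The resulting
#' null distribution calibrates how rugged the observed landscape is
#' relative to an uncorrelated one.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param nShuffles number of random permutations (default 1000).
#' @param seed integer seed.
#' @return List with \code{peakCounts} (integer sample), \code{mean},
#'   \code{sd}, and \code{upper95} (the value below which 95\% of the
#'   observations fall).
#' @export
shuffleNull <- function(landscape, nShuffles = 1000L, seed = 1L) {
    if (nShuffles < 1L) stop("nShuffles must be >= 1")
    n <- length(landscape@genotype)
    e1 <- landscape@edges[, 1L]; e2 <- landscape@edges[, 2L]
    base <- landscape@score
    counts <- .withSeed(seed, vapply(seq_len(nShuffles), function(i) {
        s <- base[sample.int(n)]
        nonpeak <- logical(n)
        nonpeak[e1[s[e2] > s[e1]]] <- TRUE
        nonpeak[e2[s[e1] > s[e2]]] <- TRUE
        sum(!nonpeak)
    }, integer(1)))
    list(peakCounts = counts, mean = mean(counts), sd = stats::sd(counts),
         upper95 = as.numeric(stats::quantile(counts, 0.95, names = FALSE)))
}
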