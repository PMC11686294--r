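# Landscape topography: basins of attraction, basin overlap, accessible
# paths, shortest-path census, epistasis squares, and one-hot PCA.

# Directed edge matrix (from, to) of traversable steps. Strict uphill edges
# always; neutral edges become traversable in both directions only when a
# noise model is active (indistinguishable steps are permitted).
.directedEdges <- function(landscape,
                           includeNeutral = !is.na(landscape@noiseScale)) {
    e <- landscape@edges; st <- landscape@edgeState
    out <- rbind(e[st == 1L, , drop = FALSE],
                 e[st == 2L, 2:1, drop = FALSE])
    if (includeNeutral && any(st == 0L))
        out <- rbind(out, e[st == 0L, , drop = FALSE],
                     e[st == 0L, 2:1, drop = FALSE])
    out
}

.uphillIgraph <- function(landscape, includeNeutral = !is.na(landscape@noiseScale)) {
    n <- length(landscape@genotype)
    g <- igraph::graph_from_edgelist(.directedEdges(landscape, includeNeutral),
                                     directed = TRUE)
    igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
}

.undirectedIgraph <- function(landscape) {
    n <- length(landscape@genotype)
    g <- igraph::graph_from_edgelist(landscape@edges, directed = FALSE)
    igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
}

.nodeIndex <- function(landscape, genotype) {
    i <- match(genotype, landscape@genotype)
    if (anyNA(i)) stop("genotype(s) not in landscape: ",
                       paste(genotype[is.na(i)], collapse = ", "))
    i
}

#' Basin of attraction of a peak
#'
#' The basin of a peak comprises every non-peak genotype from which at least
#' one accessible (monotonically uphill) mutational path to the peak exists.
#' Computed by reverse reachability over the directed uphill edges. The
#' basin fraction uses the number of non-peak genotypes in the landscape as
#' its denominator.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param peak a peak genotype (must be a local maximum).
#' @return List with \code{peak}, \code{members} (character; peak-labelled
#'   nodes excluded), \code{size}, and \code{fraction}.
#' @export
basinOfAttraction <- function(landscape, peak) {
    i <- .nodeIndex(landscape, peak)
    if (!landscape@isPeak[i]) stop("'", peak, "' is not a peak")
    g <- .uphillIgraph(landscape)
    reach <- as.integer(igraph::subcomponent(g, i, mode = "in"))
    members <- setdiff(reach, which(landscape@isPeak))
    nonPeak <- sum(!landscape@isPeak)
    list(peak = peak, members = landscape@genotype[members],
         size = length(members),
         fraction = if (nonPeak) length(members) / nonPeak else NA_real_)
}

#' Jaccard overlap between two basins of attraction
#'
#' @param b1,b2 basins from \code{\link{basinOfAttraction}} on the same
#'   landscape.
#' @return The Jaccard index \eqn{J = |B_1 \cap B_2| / |B_1 \cup B_2|}.
#' @examples
#' b1 <- list(members = c("a","b","c")); b2 <- list(members = c("b","c","d"))
#' basinOverlap(b1, b2)  # 0.5
#' @export
basinOverlap <- function(b1, b2) {
    u <- union(b1$members, b2$members)
    if (!length(u)) stop("Jaccard index undefined: both basins are empty")
    length(intersect(b1$members, b2$members)) / length(u)
}

#' Length of the shortest accessible path to a peak
#'
#' Breadth-first search over the directed uphill edges. The result is always
#' at least the Hamming distance between the two genotypes; on a rugged
#' landscape accessible routes can be substantially longer because direct
#' neighbors may lie downhill.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param src starting genotype (not the peak itself).
#' @param peak target genotype.
#' @return Integer path length in mutational steps, or \code{NA} if the peak
#'   is not accessible from \code{src}.
#' @export
shortestAccessiblePathLength <- function(landscape, src, peak) {
    i <- .nodeIndex(landscape, src); j <- .nodeIndex(landscape, peak)
    if (i == j) stop("src must differ from peak")
    g <- .uphillIgraph(landscape)
    d <- igraph::distances(g, v = i, to = j, mode = "out")[1L, 1L]
    if (is.infinite(d)) NA_integer_ else as.integer(d)
}

#' Census of shortest paths between two genotypes
#'
#' Counts all minimum-length paths between \code{src} and \code{dst} in the
#' undirected observed network, and how many of them are accessible (score
#' strictly increasing at every step toward \code{dst}; with a noise model,
#' steps between indistinguishable genotypes are also permitted). Counting
#' uses dynamic programming over the breadth-first-search layers, so no path
#' is ever listed explicitly: on a complete landscape the total for a pair
#' at Hamming distance \eqn{d} is \eqn{d!} (40,320 at \eqn{d = 8}).
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param src,dst distinct genotypes in the same component.
#' @return List with \code{length} (the shortest-path length),
#'   \code{nTotal} and \code{nAccessible}.
#' @export
enumerateShortestPaths <- function(landscape, src, dst) {
    i <- .nodeIndex(landscape, src); j <- .nodeIndex(landscape, dst)
    if (i == j) stop("src must differ from dst")
    g <- .undirectedIgraph(landscape)
    ds <- as.numeric(igraph::distances(g, v = i, mode = "all"))
    if (is.infinite(ds[j])) stop("'", dst, "' is unreachable from '", src, "'")
    dt <- as.numeric(igraph::distances(g, v = j, mode = "all"))
    d <- ds[j]
    onPath <- ds + dt == d

    e <- landscape@edges; st <- landscape@edgeState
    keep <- onPath[e[, 1L]] & onPath[e[, 2L]]
    e <- e[keep, , drop = FALSE]; st <- st[keep]
    # orient along BFS layers (ds increasing toward dst)
    fwd <- ds[e[, 2L]] == ds[e[, 1L]] + 1
    bwd <- ds[e[, 1L]] == ds[e[, 2L]] + 1
    from <- c(e[fwd, 1L], e[bwd, 2L])
    to <- c(e[fwd, 2L], e[bwd, 1L])
    stDir <- c(st[fwd], st[bwd])
    upOk <- c(st[fwd] == 1L, st[bwd] == 2L)
    if (!is.na(landscape@noiseScale)) upOk <- upOk | stDir == 0L

    layer <- ds[from]
    nTot <- nAcc <- numeric(length(landscape@genotype))
    nTot[i] <- 1; nAcc[i] <- 1
    if (length(from)) for (k in seq_len(d) - 1) {
        sel <- layer == k
        if (!any(sel)) next
        f <- from[sel]; t <- to[sel]
        add <- rowsum(nTot[f], t)
        nTot[as.integer(rownames(add))] <- nTot[as.integer(rownames(add))] + add[, 1L]
        selA <- sel & upOk
        if (any(selA)) {
            f <- from[selA]; t <- to[selA]
            addA <- rowsum(nAcc[f], t)
            nAcc[as.integer(rownames(addA))] <-
                nAcc[as.integer(rownames(addA))] + addA[, 1L]
        }
    }
    list(length = as.integer(d), nTotal = nTot[j], nAccessible = nAcc[j])
}

#' Classify a mutational square for sign epistasis
#'
#' A square is a 4-cycle in the genotype network: a background genotype, two
#' single mutants at two positions, and the double mutant. The square is
#' first re-oriented so that its highest-scoring corner plays the role of
#' the double mutant (its diagonal opposite becomes the background). Then:
#' \emph{reciprocal sign} epistasis if both single mutants score strictly
#' below the background while the double mutant scores highest;
#' \emph{simple sign} if exactly one single mutant falls strictly below the
#' background while the other is intermediate; \emph{no sign} otherwise
#' (magnitude epistasis and additivity pooled).
#'
#' @param g,gA,gB,gAB scores of the background, the two single mutants and
#'   the double mutant (any orientation; the square is re-oriented
#'   internally). Vectors classify many squares at once.
#' @return Character vector: \code{"no_sign"}, \code{"simple_sign"} or
#'   \code{"reciprocal_sign"}.
#' @examples
#' classifyEpistasis(0, 1, 1, 2)        # no_sign (additive)
#' classifyEpistasis(0, -1, -1, 1)      # reciprocal_sign
#' classifyEpistasis(0, -1, 0.5, 1)     # simple_sign
#' @export
classifyEpistasis <- function(g, gA, gB, gAB) {
    sc <- cbind(g, gA, gB, gAB)
    top <- max.col(sc, ties.method = "first")
    # opposite corner pairs: (g, gAB) and (gA, gB)
    opp <- c(4L, 3L, 2L, 1L)[top]
    bg <- sc[cbind(seq_len(nrow(sc)), opp)]
    singleCols <- rbind(c(2L, 3L), c(1L, 4L), c(1L, 4L), c(2L, 3L))
    s1 <- sc[cbind(seq_len(nrow(sc)), singleCols[top, 1L])]
    s2 <- sc[cbind(seq_len(nrow(sc)), singleCols[top, 2L])]
    nBelow <- (s1 < bg) + (s2 < bg)
    c("no_sign", "simple_sign", "reciprocal_sign")[nBelow + 1L]
}

#' Enumerate all mutational squares of a landscape
#'
#' Finds every quadruple \{background, two single mutants, double mutant\}
#' whose four members are all present in the landscape (genotypes pairwise
#' differing at at most two fixed positions), classifies each square with
#' \code{\link{classifyEpistasis}}, and reports class proportions. Candidate
#' squares with one or more unobserved corners are skipped and counted.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @return List with \code{squares} (a \code{DataFrame}: the four genotypes,
#'   their scores' class), \code{proportions} (named numeric summing to 1
#'   over the three classes), \code{nSquares}, and \code{nSkipped}
#'   (candidate squares with observed corners missing).
#' @export
enumerateSquares <- function(landscape) {
    L <- landscape@space@length
    n <- length(landscape@genotype)
    m <- .alleleIndexMatrix(landscape@genotype, L)
    codes <- as.numeric(m %*% 4^(seq_len(L) - 1))
    score <- landscape@score
    # Precompute the 36 (allele-pair at p) x (allele-pair at q) corner layouts
    # within a 16-slot presence vector indexed by 4*allele_p + allele_q + 1.
    pairIdx <- utils::combn(4L, 2L)                 # 2 x 6
    comboCorners <- matrix(0L, 4L, 36L)             # rows: w, x, y, z
    kk <- 0L
    for (ia in 1:6) for (ib in 1:6) {
        a1 <- pairIdx[1L, ia]; a2 <- pairIdx[2L, ia]
        b1 <- pairIdx[1L, ib]; b2 <- pairIdx[2L, ib]
        kk <- kk + 1L
        comboCorners[, kk] <- c((a1 - 1L) * 4L + b1,   # w = (a1,b1)
                                (a2 - 1L) * 4L + b1,   # x = (a2,b1)
                                (a1 - 1L) * 4L + b2,   # y = (a1,b2)
                                (a2 - 1L) * 4L + b2)   # z = (a2,b2)
    }
    sq <- vector("list", 0L)
    nSkipped <- 0L
    for (p in seq_len(L - 1L)) for (q in (p + 1L):L) {
        key <- codes - m[, p] * 4^(p - 1) - m[, q] * 4^(q - 1)
        groups <- split(seq_len(n), key)
        for (idx in groups) {
            pres <- integer(16L)
            pres[m[idx, p] * 4L + m[idx, q] + 1L] <- idx
            cm <- matrix(pres[comboCorners], 4L, 36L)
            npres <- colSums(cm > 0L)
            nSkipped <- nSkipped + sum(npres >= 1L & npres < 4L)
            full <- npres == 4L
            if (any(full))
                sq[[length(sq) + 1L]] <- cm[, full, drop = FALSE]
        }
    }
    if (!length(sq)) {
        return(list(squares = S4Vectors::DataFrame(), proportions =
            c(no_sign = NA_real_, simple_sign = NA_real_,
              reciprocal_sign = NA_real_),
            nSquares = 0L, nSkipped = nSkipped))
    }
    corners <- do.call(cbind, sq)
    w <- corners[1L, ]; x <- corners[2L, ]; y <- corners[3L, ]
    z <- corners[4L, ]
    cls <- classifyEpistasis(score[w], score[x], score[y], score[z])
    squares <- S4Vectors::DataFrame(
        background = landscape@genotype[w],
        singleA = landscape@genotype[x],
        singleB = landscape@genotype[y],
        double = landscape@genotype[z],
        class = cls)
    tab <- table(factor(cls, levels = c("no_sign", "simple_sign",
                                        "reciprocal_sign")))
    list(squares = squares,
         proportions = stats::setNames(as.numeric(tab) / length(cls),
                                       names(tab)),
         nSquares = length(cls), nSkipped = nSkipped)
}

#' One-hot PCA embedding of a genotype set
#'
#' Encodes each genotype as a binary vector of length \eqn{4L} (one
#' indicator per position-allele pair) and runs principal component
#' analysis. In combinatorially complete sequence spaces each component
#' explains only a small share of the variance, so the embedding is a
#' coarse map of where (e.g.) peak genotypes sit relative to the rest.
#'
#' @param genotypes character vector (>= 2, uniform length).
#' @param scores optional numeric vector attached to the returned
#'   coordinates (for colouring by repression).
#' @return List with \code{coordinates} (n x k PC score matrix, with
#'   \code{scores} attached as an attribute when supplied) and
#'   \code{explainedVariance} (ratios summing to 1).
#' @export
onehotPCA <- function(genotypes, scores = NULL) {
    if (length(genotypes) < 2L) stop("need at least 2 genotypes")
    L <- nchar(genotypes[1L])
    m <- .alleleIndexMatrix(genotypes, L)
    X <- matrix(0L, length(genotypes), 4L * L)
    for (p in seq_len(L))
        X[cbind(seq_along(genotypes), (p - 1L) * 4L + m[, p] + 1L)] <- 1L
    colnames(X) <- paste0("pos", rep(seq_len(L), each = 4L), "_",
                          rep(DNA_ALPHABET, L))
    if (all(apply(X, 2L, function(col) length(unique(col)) == 1L)))
        stop("zero total variance: all genotypes identical")
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2
    coords <- pc$x
    if (!is.null(scores)) attr(coords, "scores") <- scores
    list(coordinates = coords, explainedVariance = ev / sum(ev))
}
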