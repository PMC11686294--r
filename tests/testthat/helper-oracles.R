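# Independent oracles and fixture builders. These deliberately avoid the
# package's internal encoding/edge machinery: neighbors are produced by
# string surgery and peaks by a direct all-neighbor scan, so the two
# implementations can disagree.

NTS <- c("A", "C", "G", "T")

# All 3L Hamming-1 neighbor strings of one genotype.
stringNeighbors <- function(g) {
    ch <- strsplit(g, "")[[1]]
    out <- character(0)
    for (p in seq_along(ch)) for (a in setdiff(NTS, ch[p])) {
        x <- ch; x[p] <- a
        out <- c(out, paste(x, collapse = ""))
    }
    out
}

# Brute-force peak scan over an observed genotype set: a genotype is a peak
# iff none of its observed neighbors scores strictly higher.
bruteForcePeaks <- function(scores) {
    g <- names(scores)
    vapply(g, function(gi) {
        nb <- intersect(stringNeighbors(gi), g)
        all(scores[nb] < scores[gi])
    }, logical(1))
}

# Scored landscape from a named score vector.
scoredLandscape <- function(scores, L = nchar(names(scores)[1])) {
    buildNetwork(scores, genotypeSpace(L, context = NA))
}

# A 3-node path graph (AA - AC - CC) with the given scores.
pathLandscape <- function(scores = c(1, 2, 3)) {
    scoredLandscape(stats::setNames(scores, c("AA", "AC", "CC")))
}

# Exact uniform-walk endpoint distribution by dynamic programming over nodes
# in decreasing score order: from a non-peak the walk moves to each strictly
# uphill neighbor with equal probability. Returns an n x nPeaks matrix.
exactUniformEndpointProbs <- function(landscape) {
    g <- genotypes(landscape)
    s <- unname(nodeScores(landscape))
    pk <- which(isPeak(landscape))
    n <- length(g)
    # uphill out-neighbors per node, computed from string neighbors
    P <- matrix(0, n, length(pk), dimnames = list(g, g[pk]))
    ord <- order(s, decreasing = TRUE)
    for (i in ord) {
        nb <- match(intersect(stringNeighbors(g[i]), g), g)
        up <- nb[s[nb] > s[i]]
        if (!length(up)) {
            j <- match(i, pk)
            if (!is.na(j)) P[i, j] <- 1
        } else {
            P[i, ] <- colMeans(P[up, , drop = FALSE])
        }
    }
    P
}

# Build a BinCountTable directly from a list of per-replicate count
# matrices (rows: genotypes, cols: bins).
makeCountTable <- function(mats, L = nchar(rownames(mats[[1]])[1])) {
    names(mats) <- paste0("rep", seq_along(mats))
    nb <- ncol(mats[[1]])
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = lapply(mats, function(m) {
            storage.mode(m) <- "integer"; m
        }),
        colData = S4Vectors::DataFrame(bin = seq_len(nb),
            row.names = sprintf("bin_%02d", seq_len(nb))))
    out <- new("BinCountTable", se)
    S4Vectors::metadata(out) <- list(space = genotypeSpace(L, context = NA))
    out
}

# A count matrix concentrating `total` reads in one bin.
oneBinCounts <- function(total, bin, nBins = 13L) {
    m <- matrix(0L, 1L, nBins)
    m[1L, bin] <- as.integer(total)
    m
}

emptyLandscape <- function() {
    new("Landscape", space = genotypeSpace(2, context = NA),
        genotype = character(0), score = numeric(0), tau = numeric(0),
        edges = matrix(integer(0), 0, 2), edgeState = integer(0),
        isPeak = logical(0), plateauId = integer(0),
        relConnectivity = numeric(0), noiseScale = NA_real_,
        provenance = list())
}
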