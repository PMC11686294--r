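# Basins, accessible paths, shortest-path census, epistasis squares, PCA.

test_that("basins collect exactly the genotypes with uphill paths to a peak", {
    ls <- pathLandscape(c(1, 2, 3))
    b <- basinOfAttraction(ls, "CC")
    expect_setequal(b$members, c("AA", "AC"))
    expect_equal(b$size, 2L)
    expect_equal(b$fraction, 1)
    expect_error(basinOfAttraction(ls, "AA"), "not a peak")

    # complete additive landscape: the unique peak's basin is everything else
    set.seed(14)
    w <- matrix(runif(16), 4, 4, dimnames = list(NTS, NULL))
    lsa <- buildNetwork(makeAdditiveLandscape(genotypeSpace(4, context = NA), w))
    ba <- basinOfAttraction(lsa, peaks(lsa))
    expect_equal(ba$size, 255L)
    expect_equal(ba$fraction, 1)
})

test_that("basin membership is closed under uphill reachability", {
    tr <- makeHoCLandscape(genotypeSpace(3, context = NA), seed = 18)
    ls <- buildNetwork(tr)
    for (p in utils::head(peaks(ls), 3)) {
        b <- basinOfAttraction(ls, p)
        for (m in utils::head(b$members, 10)) {
            expect_false(is.na(shortestAccessiblePathLength(ls, m, p)))
        }
    }
})

test_that("basin overlap is the Jaccard index", {
    expect_equal(basinOverlap(list(members = c("a", "b", "c")),
                              list(members = c("a", "b", "c"))), 1)
    expect_equal(basinOverlap(list(members = "a"), list(members = "b")), 0)
    expect_equal(basinOverlap(list(members = c("a", "b", "c")),
                              list(members = c("b", "c", "d"))), 0.5)
    expect_error(basinOverlap(list(members = character(0)),
                              list(members = character(0))), "empty")
})

test_that("shortest accessible paths detour around downhill neighbors", {
    ls <- pathLandscape(c(1, 2, 3))
    expect_equal(shortestAccessiblePathLength(ls, "AC", "CC"), 1L)
    # fixture: both direct intermediates lie downhill; the only accessible
    # route makes a two-step detour (length = Hamming distance + 2)
    sc <- c(AA = 1, AT = 0.5, TA = 0.4, AG = 2, GG = 3, GT = 4, TT = 5)
    lsd <- scoredLandscape(sc)
    expect_equal(shortestAccessiblePathLength(lsd, "AA", "TT"), 4L)
    expect_true(is.na(shortestAccessiblePathLength(lsd, "AT", "TA")))
    expect_error(shortestAccessiblePathLength(lsd, "AA", "AA"), "differ")
})

test_that("accessible-path lengths agree with exhaustive path enumeration", {
    # oracle: list all simple shortest->longer paths with igraph and find the
    # shortest strictly-increasing one
    tr <- makeHoCLandscape(genotypeSpace(2, context = NA), seed = 25)
    set.seed(26)
    sub <- sample(genotypes(tr), 10)   # sparse subgraph keeps the census small
    ls <- scoredLandscape(trueRepression(tr)[sub])
    g <- igraph::graph_from_edgelist(ls@edges, directed = FALSE)
    s <- unname(nodeScores(ls)); gt <- genotypes(ls)
    pk <- which(isPeak(ls))[1]
    for (src in utils::head(which(!isPeak(ls)), 8)) {
        if (src == pk) next
        paths <- igraph::all_simple_paths(g, from = src, to = pk)
        lens <- vapply(paths, function(p) {
            v <- as.integer(p)
            if (all(diff(s[v]) > 0)) length(v) - 1L else NA_integer_
        }, integer(1))
        oracle <- if (all(is.na(lens))) NA_integer_ else
            min(lens, na.rm = TRUE)
        expect_identical(shortestAccessiblePathLength(ls, gt[src], gt[pk]),
                         oracle)
    }
})

test_that("shortest-path census counts d! direct paths on complete spaces", {
    g <- enumerateGenotypes(genotypeSpace(4, context = NA))
    set.seed(3)
    ls <- scoredLandscape(stats::setNames(runif(256), g))
    for (pair in list(c("AAAA", "CAAA"), c("AAAA", "CCAA"),
                      c("AAAA", "CCCA"), c("AAAA", "CCCC"))) {
        res <- enumerateShortestPaths(ls, pair[1], pair[2])
        expect_equal(res$nTotal, factorial(res$length))
    }
    expect_equal(enumerateShortestPaths(ls, "AAAA", "AAAC")$nTotal, 1)
    # on a complete additive landscape every shortest path to the summit is
    # accessible
    w <- matrix(runif(16), 4, 4, dimnames = list(NTS, NULL))
    lsa <- buildNetwork(makeAdditiveLandscape(genotypeSpace(4, context = NA), w))
    top <- peaks(lsa)
    for (src in sample(setdiff(genotypes(lsa), top), 5)) {
        res <- enumerateShortestPaths(lsa, src, top)
        expect_equal(res$nAccessible, res$nTotal)
        expect_equal(res$nTotal, factorial(res$length))
    }
})

test_that("path census agrees with explicit enumeration on incomplete graphs", {
    tr <- makeHoCLandscape(genotypeSpace(2, context = NA), seed = 5)
    set.seed(6)
    keep <- sample(genotypes(tr), 12)
    sc <- trueRepression(tr)[keep]
    ls <- scoredLandscape(sc)
    g <- igraph::graph_from_edgelist(ls@edges, directed = FALSE)
    s <- unname(nodeScores(ls)); gt <- genotypes(ls)
    comp <- igraph::components(g)$membership
    pairs <- which(outer(comp, comp, "==") & upper.tri(diag(length(gt))),
                   arr.ind = TRUE)
    set.seed(7)
    for (k in sample(nrow(pairs), min(10, nrow(pairs)))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        all_sp <- igraph::all_shortest_paths(g, from = i, to = j)$vpaths
        acc <- sum(vapply(all_sp, function(p)
            all(diff(s[as.integer(p)]) > 0), logical(1)))
        res <- enumerateShortestPaths(ls, gt[i], gt[j])
        expect_equal(res$nTotal, length(all_sp))
        expect_equal(res$nAccessible, acc)
    }
})

test_that("pairwise distances match the brute-force census", {
    expect_equal(pairwiseDistanceDistribution(c("AAAA", "AAAT"))$mean, 1)
    g <- enumerateGenotypes(genotypeSpace(2, context = NA))
    # brute-force oracle over all unordered pairs
    d <- combn(g, 2, function(p)
        sum(strsplit(p[1], "")[[1]] != strsplit(p[2], "")[[1]]))
    res <- pairwiseDistanceDistribution(g)
    expect_equal(res$mean, mean(d))           # = 1.6 for the complete L=2 space
    expect_equal(sort(res$distances), sort(as.vector(d)))
    expect_error(pairwiseDistanceDistribution("AA"), "at least 2")
})

test_that("epistasis squares classify by how many single mutants fall below the background", {
    expect_equal(classifyEpistasis(0, 1, 1, 2), "no_sign")
    expect_equal(classifyEpistasis(0, -1, -1, 1), "reciprocal_sign")
    expect_equal(classifyEpistasis(0, -1, 0.5, 1), "simple_sign")
    # orientation: the highest corner is re-assigned as the double mutant
    expect_equal(classifyEpistasis(2, 1, 1, 0), "no_sign")
    expect_equal(classifyEpistasis(1, 0, 0, -1),
                 classifyEpistasis(-1, 0, 0, 1))
})

test_that("square enumeration matches the 4-cycle census and classifies additivity", {
    # complete L=2 space: 6 allele pairs at each of 2 positions -> 36 squares
    g <- enumerateGenotypes(genotypeSpace(2, context = NA))
    set.seed(8)
    ls <- scoredLandscape(stats::setNames(runif(16), g))
    sq <- enumerateSquares(ls)
    expect_equal(sq$nSquares, 36L)
    expect_equal(sum(sq$proportions), 1)
    # purely additive landscape: no sign epistasis of either kind
    w <- matrix(runif(12), 4, 3, dimnames = list(NTS, NULL))
    lsa <- buildNetwork(makeAdditiveLandscape(genotypeSpace(3, context = NA), w))
    sqa <- enumerateSquares(lsa)
    expect_equal(unname(sqa$proportions["no_sign"]), 1)
    # missing corners are skipped and counted
    sub <- scoredLandscape(stats::setNames(runif(10), g[1:10]))
    sqs <- enumerateSquares(sub)
    expect_gt(sqs$nSkipped, 0)
})

test_that("multi-peaked complete landscapes contain reciprocal sign epistasis", {
    for (seed in 1:5) {
        tr <- makeHoCLandscape(genotypeSpace(3, context = NA), seed = 40 + seed)
        ls <- buildNetwork(tr)
        if (sum(isPeak(ls)) >= 2) {
            sq <- enumerateSquares(ls)
            expect_gt(sq$proportions["reciprocal_sign"], 0)
        }
    }
})

test_that("one-hot PCA explains variance consistently", {
    pc <- onehotPCA(c("AAAA", "TTTT"))
    expect_equal(pc$explainedVariance[1], 1)
    expect_equal(sum(pc$explainedVariance), 1)
    tr <- makeHoCLandscape(genotypeSpace(3, context = NA), seed = 2)
    pc2 <- onehotPCA(genotypes(tr), trueRepression(tr))
    expect_equal(sum(pc2$explainedVariance), 1)
    expect_true(all(diff(pc2$explainedVariance) < 1e-8))  # non-increasing
    expect_error(onehotPCA(c("AA", "AA", "AA")), "zero total variance")
    expect_error(onehotPCA("AA"), "at least 2")
})
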