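# Ground-truth landscape models and the sort-seq forward simulation.

test_that("additive landscapes score genotypes as sums of site weights", {
    w1 <- matrix(0:3, 4, 1, dimnames = list(NTS, NULL))
    tr <- makeAdditiveLandscape(genotypeSpace(1, context = NA), w1)
    expect_equal(unname(trueRepression(tr)[c("A", "C", "G", "T")]),
                 c(0, 1, 2, 3))
    ls <- buildNetwork(tr)
    expect_identical(peaks(ls), "T")

    # degenerate flat case: all weights zero, every genotype one plateau
    w0 <- matrix(0, 4, 2, dimnames = list(NTS, NULL))
    tr0 <- makeAdditiveLandscape(genotypeSpace(2, context = NA), w0)
    expect_true(all(trueRepression(tr0) == 0))
    ls0 <- buildNetwork(tr0)
    expect_true(all(isPeak(ls0)))
    expect_equal(length(unique(plateauIds(ls0))), 1L)
})

test_that("additive landscapes with distinct best-allele margins have one peak", {
    set.seed(11)
    for (rep in 1:5) {
        w <- matrix(runif(16), 4, 4, dimnames = list(NTS, NULL))
        tr <- makeAdditiveLandscape(genotypeSpace(4, context = NA), w)
        sc <- trueRepression(tr)
        expect_equal(sum(bruteForcePeaks(sc)), 1L)  # exhaustive 256-node scan
        expect_equal(sum(isPeak(buildNetwork(tr))), 1L)
    }
    expect_error(makeAdditiveLandscape(genotypeSpace(2, context = NA),
                                       matrix(1, 4, 1)),
                 "4 x L")
})

test_that("HoC landscapes are i.i.d., seeded, and match the peak-count expectation", {
    sp <- genotypeSpace(4, context = NA)
    a <- makeHoCLandscape(sp, seed = 42)
    b <- makeHoCLandscape(sp, seed = 42)
    expect_identical(trueRepression(a), trueRepression(b))
    expect_false(identical(trueRepression(a),
                           trueRepression(makeHoCLandscape(sp, seed = 43))))

    # E[peaks] = 4^L/(3L+1) on the complete Hamming graph
    for (L in c(3, 4)) {
        nrep <- if (L == 3) 150 else 80
        counts <- vapply(seq_len(nrep), function(i) {
            tr <- makeHoCLandscape(genotypeSpace(L, context = NA), seed = 1000 + i)
            sum(isPeak(buildNetwork(tr)))
        }, numeric(1))
        expected <- 4^L / (3 * L + 1)
        se <- sd(counts) / sqrt(nrep)
        expect_lt(abs(mean(counts) - expected), 4 * se + 0.5)
    }
})

test_that("NK landscapes reduce to additive at K=0 and to HoC-like ruggedness at K=L-1", {
    sp <- genotypeSpace(4, context = NA)
    tr0 <- makeNKLandscape(sp, K = 0, seed = 5)
    # K = 0: per-site component tables are exactly additive site weights
    w <- do.call(cbind, tr0@modelParams$componentTables)
    rownames(w) <- NTS
    trAdd <- makeAdditiveLandscape(sp, w / 4)
    expect_equal(sum(isPeak(buildNetwork(tr0))),
                 sum(isPeak(buildNetwork(trAdd))))

    # reproducible component tables
    expect_identical(trueRepression(makeNKLandscape(sp, K = 2, seed = 9)),
                     trueRepression(makeNKLandscape(sp, K = 2, seed = 9)))

    # K = L-1: mean peak count statistically indistinguishable from HoC
    nrep <- 60
    counts <- vapply(seq_len(nrep), function(i)
        sum(isPeak(buildNetwork(makeNKLandscape(sp, K = 3, seed = 2000 + i)))),
        numeric(1))
    expected <- 4^4 / 13
    se <- sd(counts) / sqrt(nrep)
    expect_lt(abs(mean(counts) - expected), 4 * se + 0.5)

    expect_error(makeNKLandscape(sp, K = 4), "K must satisfy")
})

test_that("simulated sort-seq conserves reads, is seeded, and respects gates", {
    sp <- genotypeSpace(3, context = NA)
    tr <- makeHoCLandscape(sp, seed = 3)
    cfg <- sortSeqConfig(seed = 8, cellsPerGenotype = 40L)
    bc <- simulateSortSeq(tr, cfg)
    reads <- vapply(as.list(SummarizedExperiment::assays(bc)), sum, numeric(1))
    expect_true(all(reads == S4Vectors::metadata(bc)$readsTotal))

    bc2 <- simulateSortSeq(tr, cfg)
    expect_identical(SummarizedExperiment::assays(bc),
                     SummarizedExperiment::assays(bc2))

    # noiseless limit: a genotype whose expected fluorescence sits inside
    # gate 5 puts every read into bin 5
    gates <- 2^seq(log2(100), log2(2^13 * 100), length.out = 12)
    cfg0 <- sortSeqConfig(seed = 1, cellNoiseSd = 0, replicateNoiseSd = 0,
                          gateBoundaries = gates, cellsPerGenotype = 20L,
                          readsTotal = 200)
    # pick S so fluorMax * 2^(-8 S) falls between gates[4] and gates[5]
    target <- sqrt(gates[4] * gates[5])
    S <- log2(cfg0@fluorMax / target) / cfg0@logSlope
    tr1 <- new("GroundTruthLandscape", space = genotypeSpace(1, context = NA),
               genotype = "A", trueRepression = S, modelKind = "HoC",
               modelParams = list(), seed = 1L)
    bc0 <- simulateSortSeq(tr1, cfg0)
    cnt <- SummarizedExperiment::assay(bc0, 1)
    expect_equal(unname(cnt[1, 5]), 200L)
    expect_equal(sum(cnt), 200L)
})

test_that("higher true repression lowers the expected weighted-bin index", {
    sp <- genotypeSpace(2, context = NA)
    g <- enumerateGenotypes(sp)
    tr <- new("GroundTruthLandscape", space = sp, genotype = g,
              trueRepression = seq(0, 1.25, length.out = length(g)),
              modelKind = "HoC", modelParams = list(), seed = 1L)
    cfg <- sortSeqConfig(seed = 2, cellsPerGenotype = 400L,
                         replicateNoiseSd = 0, nReplicates = 1L,
                         readsTotal = 64 * 2000)
    bc <- simulateSortSeq(tr, cfg)
    e <- expressionScore(SummarizedExperiment::assay(bc, 1))
    # strong average monotone trend: expression decreases with repression
    expect_lt(cor(tr@trueRepression, e, method = "spearman"), -0.95)
})

test_that("pipeline recovery: recovered scores rank-match the truth at default depth", {
    sp <- genotypeSpace(8)
    tr <- makeHoCLandscape(sp, seed = 21)
    set.seed(77)
    sub <- sample(genotypes(tr), 400)
    bc <- simulateSortSeq(tr, sortSeqConfig(seed = 22), genotypes = sub)
    st <- suppressMessages(filterVariants(bc))
    stn <- normalizeByWildtype(st, st$genotype[which.max(st$meanR)])
    truth <- trueRepression(tr)[stn$genotype]
    expect_gte(cor(truth, stn$S, method = "spearman"), 0.9)
    # exchangeability: scores of equal-truth genotypes converge with depth
    expect_equal(max(stn$S), 1)  # wild type chosen as strongest survivor
})
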