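# Adaptive walk engines, Kimura fixation, summaries, noise sweep.

test_that("greedy walks climb deterministically to the best neighbor", {
    ls <- pathLandscape(c(1, 2, 3))
    w <- greedyWalk(ls, "AA")
    expect_equal(w@trajectory, c("AA", "AC", "CC"))
    expect_equal(w@steps, 2L)
    expect_true(w@endpointIsPeak)
    # starting on a peak is a zero-step walk
    w0 <- greedyWalk(ls, "CC")
    expect_equal(w0@trajectory, "CC")
    expect_equal(w0@steps, 0L)
    # determinism on a rugged landscape
    tr <- makeHoCLandscape(genotypeSpace(3, context = NA), seed = 3)
    lsr <- buildNetwork(tr)
    st <- genotypes(lsr)[which.min(nodeScores(lsr))]
    expect_identical(greedyWalk(lsr, st)@trajectory,
                     greedyWalk(lsr, st)@trajectory)
    # each greedy step takes the maximal available gain
    w2 <- greedyWalk(lsr, st)
    s <- nodeScores(lsr)
    for (i in seq_len(w2@steps)) {
        cur <- w2@trajectory[i]
        nb <- intersect(stringNeighbors(cur), genotypes(lsr))
        expect_equal(s[w2@trajectory[i + 1]],
                     max(s[nb]), ignore_attr = TRUE)
    }
})

test_that("uniform walks pick uphill neighbors with equal probability", {
    # AA(0) has exactly two uphill neighbors AC(1) and CA(1); both are peaks
    ls <- scoredLandscape(c(AA = 0, AC = 1, CA = 1))
    set.seed(100)
    ends <- vapply(1:4000, function(i) uniformWalk(ls, "AA")@endpoint,
                   character(1))
    p <- mean(ends == "AC")
    expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 4000))
    # a single uphill neighbor is taken with probability 1
    ls1 <- pathLandscape(c(1, 2, 3))
    expect_equal(uniformWalk(ls1, "AC")@endpoint, "CC")
    # trajectories increase strictly in score
    tr <- makeHoCLandscape(genotypeSpace(3, context = NA), seed = 7)
    lsr <- buildNetwork(tr)
    set.seed(5)
    for (i in 1:10) {
        w <- uniformWalk(lsr, sample(genotypes(lsr), 1))
        expect_true(all(w@selectionCoefficients > 0))
        expect_true(w@endpointIsPeak)
    }
})

test_that("uniform-walk endpoint support equals basin reachability", {
    for (seed in c(51, 52)) {
        tr <- makeHoCLandscape(genotypeSpace(3, context = NA), seed = seed)
        ls <- buildNetwork(tr)
        P <- exactUniformEndpointProbs(ls)      # independent DP oracle
        pk <- peaks(ls)
        for (st in utils::head(genotypes(ls)[!isPeak(ls)], 12)) {
            support <- colnames(P)[P[st, ] > 0]
            reachable <- pk[vapply(pk, function(p)
                st %in% basinOfAttraction(ls, p)$members, logical(1))]
            expect_setequal(support, reachable)
        }
    }
})

test_that("Kimura fixation probability has the exact neutral limit and guards", {
    for (N in c(2, 100, 1e5, 1e8)) {
        expect_equal(kimuraFixationProbability(0, N), 1 / N,
                     tolerance = 1e-12)
    }
    # large N, beneficial: denominator ~ 1
    expect_equal(kimuraFixationProbability(0.01, 1e8), -expm1(-0.02),
                 tolerance = 1e-6)
    # strongly deleterious underflows to zero without NaN
    f <- kimuraFixationProbability(-0.1, 1e8)
    expect_identical(f, 0)
    expect_false(is.nan(kimuraFixationProbability(-1e-9, 1e8)))
    # monotone increasing in s, bounded by 2s behaviour
    sgrid <- seq(-0.05, 0.05, by = 0.001)
    fg <- kimuraFixationProbability(sgrid, 1000)
    expect_true(all(diff(fg) > 0))
    # for s > 0 the finite-N probability exceeds the N -> Inf limit 1-e^(-2s)
    pos <- sgrid > 0
    expect_true(all(fg[pos] >= -expm1(-2 * sgrid[pos]) - 1e-12))
    expect_equal(kimuraFixationProbability(sgrid[pos], 1e9),
                 -expm1(-2 * sgrid[pos]), tolerance = 1e-6)
    expect_error(kimuraFixationProbability(0, 1), "N must be")
})

test_that("Kimura walks fix neutrally at rate 1/N on flat landscapes", {
    g <- enumerateGenotypes(genotypeSpace(2, context = NA))
    ls <- scoredLandscape(stats::setNames(rep(1, 16), g))
    N <- 10
    set.seed(9)
    fixations <- vapply(1:40, function(i)
        kimuraWalk(ls, "AA", N = N, maxSteps = 100)@steps, numeric(1))
    # each of the 100 proposals fixes with probability 1/N = 0.1
    expect_lt(abs(mean(fixations) - 10), 3 * sqrt(100 * 0.1 * 0.9 / 40))
})

test_that("large populations never fix deleterious steps; drift crosses valleys", {
    tr <- makeHoCLandscape(genotypeSpace(3, context = NA), seed = 13)
    ls <- buildNetwork(tr)
    set.seed(17)
    w <- kimuraWalk(ls, genotypes(ls)[1], N = 1e8, maxSteps = 300)
    expect_true(all(w@selectionCoefficients > 0))

    # shallow valley: AA(1) - AC(0.995) - CC(2); crossing decays with N
    lsv <- scoredLandscape(c(AA = 1, AC = 0.995, CC = 2))
    crossFrac <- vapply(c(100, 1e4, 1e8), function(N) {
        set.seed(23)
        mean(vapply(1:150, function(i)
            "CC" %in% kimuraWalk(lsv, "AA", N = N, maxSteps = 60)@trajectory,
            logical(1)))
    }, numeric(1))
    expect_true(all(diff(crossFrac) <= 0))
    expect_gt(crossFrac[1], crossFrac[3])
})

test_that("mutation bias reweights Kimura proposals", {
    # from AA, neighbors AC/AG/AT/CA/GA/TA; forbid all transversions so only
    # A->G changes can be proposed
    g <- c("AA", "AC", "AG", "AT", "CA", "GA", "TA")
    ls <- scoredLandscape(stats::setNames(c(0, 1, 1, 1, 1, 1, 1), g))
    bias <- matrix(0, 4, 4)
    bias[1, 3] <- 1  # A -> G only
    set.seed(3)
    for (i in 1:5) {
        w <- kimuraWalk(ls, "AA", N = 100, maxSteps = 30, biasMatrix = bias)
        expect_true(all(w@trajectory %in% c("AA", "AG", "GA")))
    }
    expect_error(kimuraWalk(ls, "AA", biasMatrix = matrix(0, 4, 4)),
                 "positive off-diagonal")
})

test_that("walk batches are seeded reproducibly and summarised correctly", {
    set.seed(1)
    w <- matrix(runif(12), 4, 3, dimnames = list(NTS, NULL))
    ls <- buildNetwork(makeAdditiveLandscape(genotypeSpace(3, context = NA), w))
    r1 <- runWalks(ls, "uniform", walksPerStart = 2, seed = 77)
    r2 <- runWalks(ls, "uniform", walksPerStart = 2, seed = 77)
    expect_identical(vapply(r1, function(x) x@endpoint, character(1)),
                     vapply(r2, function(x) x@endpoint, character(1)))
    # single-peaked additive landscape: every walk ends on the summit
    thr <- stats::median(nodeScores(ls))
    sm <- walkSummary(r1, ls, highThreshold = thr)
    expect_equal(sm$fractionHigh, 1)
    expect_true(all(sm$distinctHighPeaksPerStart == 1L))
    expect_equal(sum(sm$peakAttainment), sm$nWalks)
    expect_error(walkSummary(list(), ls), "no walks")
})

test_that("noise sweep reproduces the noise-free landscape at scale 0", {
    tr <- makeHoCLandscape(genotypeSpace(3, context = NA), seed = 33)
    ls <- buildNetwork(tr)
    tau <- abs(rnorm(64, 0, 0.03))
    ls@tau <- tau
    sw <- noiseSweep(ls, scales = c(0, 1, 1.5), nStarts = 10,
                     walksPerStart = 5, maxSteps = 50, seed = 4)
    tab <- sw$table
    expect_equal(tab$peaks[tab$scale == 0], sum(isPeak(ls)))
    expect_identical(sw$landscapes[[1]]@edgeState, ls@edgeState)
    # the local-maximum set grows as distinguishability decays with scale,
    # while strict peaks (distinguishably above all neighbors) shrink
    expect_true(all(diff(tab$peaks) >= 0))
    expect_true(all(diff(tab$strictPeaks) <= 0))
    # huge noise: every pair indistinguishable, one landscape-wide plateau
    lsBig <- applyNoiseModel(ls, scale = 1e6)
    pkBig <- findPeaks(lsBig)
    expect_equal(pkBig$peakCount, 64L)
    expect_equal(pkBig$plateauCount, 1L)
    expect_equal(pkBig$meanBreadth, 64)
})
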