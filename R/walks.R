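# Adaptive walks: greedy (clonal-interference proxy), uniform SSWM, and
# Kimura-fixation walks with drift, plus summaries and the noise sweep.

# Strict-uphill adjacency list (out-neighbors with distinguishably higher
# score), used by all walk engines.
.uphillAdjacency <- function(landscape) {
    n <- length(landscape@genotype)
    de <- .directedEdges(landscape, includeNeutral = FALSE)
    adj <- split(de[, 2L], factor(de[, 1L], levels = seq_len(n)))
    names(adj) <- NULL
    adj
}

# Full neighbor adjacency (all observed Hamming-1 neighbors), for Kimura
# proposals.
.neighborAdjacency <- function(landscape) {
    n <- length(landscape@genotype)
    e <- landscape@edges
    adj <- split(c(e[, 2L], e[, 1L]),
                 factor(c(e[, 1L], e[, 2L]), levels = seq_len(n)))
    names(adj) <- NULL
    adj
}

.walkResult <- function(landscape, traj, mode, highThreshold,
                        visitedPeaks = NULL) {
    g <- landscape@genotype
    end <- traj[length(traj)]
    endPeak <- landscape@isPeak[end]
    s <- diff(landscape@score[traj])
    if (is.null(visitedPeaks))
        visitedPeaks <- unique(g[traj[landscape@isPeak[traj]]])
    new("WalkResult", start = g[traj[1L]], trajectory = g[traj],
        steps = length(traj) - 1L, endpoint = g[end],
        endpointIsPeak = endPeak,
        endpointIsHighPeak = endPeak && landscape@score[end] > highThreshold,
        selectionCoefficients = s, visitedPeaks = visitedPeaks,
        mode = mode)
}

#' Greedy adaptive walk
#'
#' From the start genotype, repeatedly steps to the neighbor with the
#' largest score increase until no neighbor is distinguishably higher (a
#' peak). Deterministic; ties in the maximal gain are broken towards the
#' lexicographically smallest genotype unless \code{tieBreak = "random"}.
#' Greedy walks proxy adaptation under clonal interference, where the
#' fittest of several contending mutations fixes.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param start starting genotype.
#' @param highThreshold score above which a peak counts as a high peak
#'   (default 1: above the wild type on the normalised scale).
#' @param tieBreak \code{"lexicographic"} (default, deterministic) or
#'   \code{"random"}.
#' @return A \linkS4class{WalkResult}.
#' @export
greedyWalk <- function(landscape, start, highThreshold = 1,
                       tieBreak = c("lexicographic", "random")) {
    tieBreak <- match.arg(tieBreak)
    adj <- .uphillAdjacency(landscape)
    s <- landscape@score
    g <- landscape@genotype
    cur <- .nodeIndex(landscape, start)
    traj <- cur
    repeat {
        nb <- adj[[cur]]
        if (!length(nb)) break
        best <- nb[s[nb] == max(s[nb])]
        cur <- if (length(best) == 1L) best
               else if (tieBreak == "lexicographic") best[order(g[best])][1L]
               else best[sample.int(length(best), 1L)]
        traj <- c(traj, cur)
    }
    .walkResult(landscape, traj, "greedy", highThreshold)
}

#' Uniform (SSWM) adaptive walk
#'
#' At each step one of the strictly uphill neighbors is chosen uniformly at
#' random; the walk terminates at a peak. This models the strong-selection
#' weak-mutation regime, where every beneficial mutation is equally likely
#' to be the next to fix.
#'
#' @inheritParams greedyWalk
#' @return A \linkS4class{WalkResult}.
#' @export
uniformWalk <- function(landscape, start, highThreshold = 1) {
    adj <- .uphillAdjacency(landscape)
    cur <- .nodeIndex(landscape, start)
    traj <- cur
    repeat {
        nb <- adj[[cur]]
        if (!length(nb)) break
        cur <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
        traj <- c(traj, cur)
    }
    .walkResult(landscape, traj, "uniform", highThreshold)
}

#' Kimura fixation probability
#'
#' Probability that a mutation with selection coefficient \eqn{s} fixes in a
#' haploid population of effective size \eqn{N}:
#' \deqn{f = \frac{1 - e^{-2s}}{1 - e^{-2Ns}},}
#' with the neutral limit \eqn{f = 1/N} at \eqn{s = 0}. Evaluated in log
#' space for strongly deleterious mutations so that very small fixation
#' probabilities underflow cleanly to 0 rather than producing NaN.
#'
#' @param s selection coefficient(s): the score difference between the
#'   proposed and the current genotype.
#' @param N effective population size (>= 2).
#' @return Fixation probability/ies in \code{[0, 1)}.
#' @examples
#' kimuraFixationProbability(0, 100)          # 1/100
#' kimuraFixationProbability(0.01, 1e8)       # ~ 1 - exp(-0.02)
#' @export
kimuraFixationProbability <- function(s, N) {
    if (N < 2) stop("N must be >= 2")
    f <- numeric(length(s))
    zero <- s == 0
    pos <- s > 0
    neg <- s < 0
    f[zero] <- 1 / N
    if (any(pos))
        f[pos] <- (-expm1(-2 * s[pos])) / (-expm1(-2 * N * s[pos]))
    if (any(neg)) {
        # numerator and denominator are both negative; flip signs and take
        # logs: log(expm1(x)) ~ x for large x, so huge -2Ns underflows to 0
        x <- -2 * s[neg]; xN <- -2 * N * s[neg]
        lden <- ifelse(xN > 700, xN, log(expm1(xN)))
        f[neg] <- exp(log(expm1(x)) - lden)
    }
    f
}

#' Kimura adaptive walk with genetic drift
#'
#' Runs a fixed number of mutational steps. At each step a neighbor of the
#' current genotype is proposed (uniformly, or weighted by a 4x4 mutation
#' rate matrix applied to the nucleotide change) and fixes with its Kimura
#' fixation probability; neutral and deleterious fixations are permitted,
#' so the walk can leave peaks and visit several of them. Steps without a
#' fixation still consume an iteration.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param start starting genotype.
#' @param N effective population size.
#' @param maxSteps number of proposed mutational steps (default 1000).
#' @param biasMatrix optional 4x4 non-negative relative mutation-rate matrix
#'   (rows: from-nucleotide A,C,G,T; diagonal ignored). Default: uniform.
#' @param highThreshold score above which a peak is a high peak.
#' @return A \linkS4class{WalkResult}; \code{visitedPeaks} lists every peak
#'   genotype whose node the walk occupied.
#' @export
kimuraWalk <- function(landscape, start, N = 1e8, maxSteps = 1000L,
                       biasMatrix = NULL, highThreshold = 1) {
    adj <- .neighborAdjacency(landscape)
    s <- landscape@score
    cur <- .nodeIndex(landscape, start)
    useBias <- !is.null(biasMatrix)
    if (useBias) {
        if (!is.matrix(biasMatrix) || any(dim(biasMatrix) != 4L) ||
            any(biasMatrix < 0))
            stop("biasMatrix must be a non-negative 4x4 matrix")
        diag(biasMatrix) <- 0
        if (all(biasMatrix == 0))
            stop("biasMatrix needs at least one positive off-diagonal rate")
        L <- landscape@space@length
        am <- .alleleIndexMatrix(landscape@genotype, L) + 1L
    }
    traj <- integer(maxSteps + 1L); traj[1L] <- cur
    nFix <- 0L
    visited <- logical(length(s))
    visited[cur] <- landscape@isPeak[cur]
    for (step in seq_len(maxSteps)) {
        nb <- adj[[cur]]
        if (length(nb)) {
            if (useBias) {
                wts <- vapply(nb, function(j) {
                    p <- which(am[cur, ] != am[j, ])
                    biasMatrix[am[cur, p], am[j, p]]
                }, numeric(1))
                if (sum(wts) == 0) next
                prop <- nb[sample.int(length(nb), 1L, prob = wts)]
            } else {
                prop <- if (length(nb) == 1L) nb
                        else nb[sample.int(length(nb), 1L)]
            }
            fij <- kimuraFixationProbability(s[prop] - s[cur], N)
            if (stats::runif(1L) <= fij) {
                cur <- prop
                nFix <- nFix + 1L
                traj[nFix + 1L] <- cur
                if (landscape@isPeak[cur]) visited[cur] <- TRUE
            }
        }
    }
    traj <- traj[seq_len(nFix + 1L)]
    .walkResult(landscape, traj, "kimura", highThreshold,
                visitedPeaks = landscape@genotype[visited])
}

#' Run many adaptive walks
#'
#' Convenience driver: runs \code{walksPerStart} walks of the requested mode
#' from each start genotype under a single seed, returning the list of
#' \linkS4class{WalkResult}s. Greedy walks are deterministic, so one walk
#' per start is run regardless of \code{walksPerStart}.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param mode \code{"greedy"}, \code{"uniform"} or \code{"kimura"}.
#' @param starts character vector of start genotypes; \code{NULL} means all
#'   non-peak genotypes.
#' @param walksPerStart walks per start for stochastic modes (default 1).
#' @param seed integer seed (bit-reproducible given identical inputs).
#' @param N,maxSteps,biasMatrix passed to \code{\link{kimuraWalk}}.
#' @param highThreshold high-peak score threshold (default 1).
#' @return List of \linkS4class{WalkResult}.
#' @export
runWalks <- function(landscape, mode = c("uniform", "greedy", "kimura"),
                     starts = NULL, walksPerStart = 1L, seed = 1L,
                     N = 1e8, maxSteps = 1000L, biasMatrix = NULL,
                     highThreshold = 1) {
    mode <- match.arg(mode)
    if (is.null(starts))
        starts <- landscape@genotype[!landscape@isPeak]
    if (mode == "greedy") walksPerStart <- 1L
    .withSeed(seed, {
        out <- vector("list", length(starts) * walksPerStart)
        k <- 0L
        for (st in starts) for (w in seq_len(walksPerStart)) {
            k <- k + 1L
            out[[k]] <- switch(mode,
                greedy = greedyWalk(landscape, st, highThreshold),
                uniform = uniformWalk(landscape, st, highThreshold),
                kimura = kimuraWalk(landscape, st, N, maxSteps, biasMatrix,
                                    highThreshold))
        }
        out
    })
}

#' Summarise a collection of adaptive walks
#'
#' @param results list of \linkS4class{WalkResult} from the same landscape.
#' @param landscape the \linkS4class{Landscape} the walks ran on.
#' @param highThreshold high-peak score threshold (default 1).
#' @return List with \code{fractionHigh} (walks ending at, or for Kimura
#'   walks visiting, a high peak), \code{stepDistribution},
#'   \code{endpointScores}, \code{distinctHighPeaksPerStart} (named integer),
#'   \code{visitCounts} (per-genotype node visitation counts over all
#'   trajectories), and \code{peakAttainment} (per-peak endpoint
#'   frequencies).
#' @export
walkSummary <- function(results, landscape, highThreshold = 1) {
    if (!length(results)) stop("no walks supplied")
    g <- landscape@genotype
    ends <- vapply(results, function(r) r@endpoint, character(1))
    if (!all(ends %in% g))
        stop("walks do not belong to this landscape")
    starts <- vapply(results, function(r) r@start, character(1))
    steps <- vapply(results, function(r) r@steps, integer(1))
    sc <- landscape@score[match(ends, g)]
    highPk <- g[landscape@isPeak & landscape@score > highThreshold]
    reachedHigh <- vapply(results, function(r)
        any(r@visitedPeaks %in% highPk), logical(1))
    perStart <- split(results, starts)
    distinctHigh <- vapply(perStart, function(rs)
        length(unique(unlist(lapply(rs, function(r)
            intersect(r@visitedPeaks, highPk))))), integer(1))
    visits <- table(factor(unlist(lapply(results, function(r) r@trajectory)),
                           levels = g))
    list(nWalks = length(results),
         fractionHigh = mean(reachedHigh),
         stepDistribution = table(steps),
         meanSteps = mean(steps),
         endpointScores = sc,
         distinctHighPeaksPerStart = distinctHigh,
         visitCounts = as.integer(visits),
         peakAttainment = table(factor(ends[ends %in% highPk],
                                       levels = highPk)))
}

#' Landscape and walk behaviour across noise scales
#'
#' For each noise scale, rebuilds the noise-aware landscape
#' (\code{\link{applyNoiseModel}}), recomputes peak/plateau statistics, and
#' reruns Kimura walks from the same starts with the same seed, so the
#' effect of noise on topography and navigability can be read off a single
#' table. Scale 0 reproduces the noise-free landscape.
#'
#' @param landscape a \linkS4class{Landscape} with per-genotype \code{tau}.
#' @param scales numeric vector of noise scale factors (e.g.
#'   \code{c(0, 1, 1.1, 1.25, 1.5)}).
#' @param starts start genotypes (default: sample of non-peak genotypes).
#' @param nStarts used when \code{starts} is NULL.
#' @param walksPerStart,N,maxSteps passed to the walk driver.
#' @param seed integer seed (reused at every scale).
#' @param highThreshold high-peak score threshold.
#' @return List with \code{table} (a data.frame: scale, peaks, strictPeaks,
#'   plateaus, meanBreadth, fractionHigh) and \code{landscapes} (the
#'   per-scale \linkS4class{Landscape}s).
#' @export
noiseSweep <- function(landscape, scales = c(0, 1, 1.1, 1.25, 1.5),
                       starts = NULL, nStarts = 50L, walksPerStart = 20L,
                       N = 1e8, maxSteps = 200L, seed = 1L,
                       highThreshold = 1) {
    if (any(scales < 0)) stop("scales must be non-negative")
    if (is.null(starts)) {
        nonPeak <- landscape@genotype[!landscape@isPeak]
        starts <- .withSeed(.stageSeed(seed, "sweep-starts"),
            sample(nonPeak, min(nStarts, length(nonPeak))))
    }
    rows <- vector("list", length(scales))
    lss <- vector("list", length(scales))
    for (i in seq_along(scales)) {
        ls_i <- applyNoiseModel(landscape, scale = scales[i])
        pk <- findPeaks(ls_i)
        walks <- runWalks(ls_i, "kimura", starts = starts,
                          walksPerStart = walksPerStart, seed = seed,
                          N = N, maxSteps = maxSteps,
                          highThreshold = highThreshold)
        sm <- walkSummary(walks, ls_i, highThreshold)
        rows[[i]] <- data.frame(scale = scales[i],
                                peaks = pk$peakCount,
                                strictPeaks = pk$strictPeakCount,
                                plateaus = pk$plateauCount,
                                meanBreadth = pk$meanBreadth,
                                fractionHigh = sm$fractionHigh)
        lss[[i]] <- ls_i
    }
    list(table = do.call(rbind, rows), landscapes = lss)
}
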