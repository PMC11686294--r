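# Forward model of the sort-seq experiment. Cells carrying a genotype emit
# log-normal fluorescence around a monotone-decreasing map of the genotype's
# true repression (log-linear with saturation at the autofluorescence floor),
# are sorted into gates, and reads are drawn multinomially from the gate
# occupancies, once per replicate.

#' @importFrom SummarizedExperiment SummarizedExperiment assays assay colData rowData
NULL

# Expected fluorescence (a.u.) of a genotype with repression S.
.repressionToFluor <- function(S, cfg) {
    pmax(cfg@fluorFloor, cfg@fluorMax * 2^(-cfg@logSlope * S))
}

# Gate boundaries on the fluorescence axis: bin-1 upper bound at the
# autofluorescence median, bin-nBins lower bound at the 95th percentile of the
# recorded population, interior boundaries log2-equidistant.
.deriveGates <- function(populationFluor, cfg) {
    lo <- cfg@fluorFloor
    hi <- as.numeric(stats::quantile(populationFluor, 0.95, names = FALSE))
    if (hi <= lo)
        hi <- lo * 2^(cfg@nBins - 2L)  # degenerate population: fixed ladder
    2^seq(log2(lo), log2(hi), length.out = cfg@nBins - 1L)
}

#' Simulate a sort-seq experiment from a ground-truth landscape
#'
#' For each replicate, draws per-cell fluorescence for every genotype
#' (log-normal around the repression-to-fluorescence map, plus a per
#' genotype-by-replicate log-normal factor emulating between-replicate
#' dispersion), assigns cells to fluorescence gates, and samples sequencing
#' reads multinomially from the gate occupancies so that each replicate's
#' counts sum exactly to \code{readsTotal}.
#'
#' @param truth a \linkS4class{GroundTruthLandscape}.
#' @param cfg a \linkS4class{SortSeqConfig}.
#' @param genotypes optional subset of genotypes to simulate (default: all
#'   genotypes of the truth).
#' @return A \linkS4class{BinCountTable} with one assay per replicate.
#' @examples
#' sp <- genotypeSpace(3, context = NA)
#' tr <- makeHoCLandscape(sp, seed = 1)
#' bc <- simulateSortSeq(tr, sortSeqConfig(seed = 1, cellsPerGenotype = 20L))
#' @export
simulateSortSeq <- function(truth, cfg = sortSeqConfig(), genotypes = NULL) {
    validObject(cfg)
    if (is.null(genotypes)) {
        genotypes <- truth@genotype
        S <- truth@trueRepression
    } else {
        idx <- match(genotypes, truth@genotype)
        if (anyNA(idx))
            stop("truth does not cover all requested genotypes")
        S <- truth@trueRepression[idx]
    }
    n <- length(genotypes)
    readsTotal <- if (is.na(cfg@readsTotal)) 100 * n else cfg@readsTotal
    if (readsTotal <= 0) stop("readsTotal must be positive")
    nb <- cfg@nBins
    lf0 <- log2(.repressionToFluor(S, cfg))

    .withSeed(cfg@seed, {
        # Record a reference population (replicate-like draw) to place gates,
        # unless explicit boundaries were supplied.
        gates <- if (length(cfg@gateBoundaries)) cfg@gateBoundaries else {
            ref <- rep(lf0, each = cfg@cellsPerGenotype) +
                stats::rnorm(n * cfg@cellsPerGenotype, 0, cfg@cellNoiseSd)
            .deriveGates(2^ref, cfg)
        }
        lgates <- log2(gates)
        assayList <- vector("list", cfg@nReplicates)
        for (k in seq_len(cfg@nReplicates)) {
            repEff <- stats::rnorm(n, 0, cfg@replicateNoiseSd)
            lf <- rep(lf0 + repEff, each = cfg@cellsPerGenotype) +
                stats::rnorm(n * cfg@cellsPerGenotype, 0, cfg@cellNoiseSd)
            bin <- findInterval(lf, lgates, left.open = TRUE) + 1L
            gid <- rep(seq_len(n), each = cfg@cellsPerGenotype)
            occ <- matrix(0, n, nb)
            tb <- table(factor(gid, levels = seq_len(n)),
                        factor(bin, levels = seq_len(nb)))
            occ[] <- as.numeric(tb)
            if (cfg@dropoutRate > 0) {
                drop <- stats::runif(n) < cfg@dropoutRate
                occ[drop, ] <- 0
            }
            if (sum(occ) == 0) stop("no cells survived sorting")
            reads <- stats::rmultinom(1L, size = readsTotal,
                                      prob = as.vector(occ) / sum(occ))
            cnt <- matrix(as.integer(reads), n, nb,
                          dimnames = list(genotypes, NULL))
            assayList[[k]] <- cnt
        }
        names(assayList) <- paste0("rep", seq_len(cfg@nReplicates))
        se <- SummarizedExperiment(
            assays = assayList,
            colData = S4Vectors::DataFrame(
                bin = seq_len(nb),
                row.names = sprintf("bin_%02d", seq_len(nb))))
        out <- new("BinCountTable", se)
        metadata(out) <- list(space = truth@space, config = cfg,
                              gateBoundaries = gates,
                              readsTotal = readsTotal,
                              seed = cfg@seed)
        out
    })
}
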