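# Sort-seq scoring: weighted-bin expression estimates, the reversed
# repression scale, replicate filters, wild-type normalisation, and
# frequency/information-content matrices.

#' Weighted-bin expression score
#'
#' Estimates the expression level driven by a genotype as the read-weighted
#' mean bin index, \eqn{e = \sum_i x_i w_i / \sum_i x_i}, with integer bin
#' weights \eqn{w_i = 1, \ldots, n}. Sequences appear in several bins because
#' of sorting errors and expression noise; the weighted mean pools them.
#'
#' @param counts a non-negative integer vector of per-bin read counts, or a
#'   matrix with one row per genotype and one column per bin.
#' @param weights bin weights (default \code{1:ncol}).
#' @return Numeric expression score(s) in \code{[1, nBins]}.
#' @examples
#' expressionScore(c(0, 0, 5, 5, 0))  # 3.5
#' @export
expressionScore <- function(counts, weights = NULL) {
    if (is.vector(counts)) counts <- matrix(counts, nrow = 1L)
    if (any(counts < 0)) stop("negative counts")
    if (is.null(weights)) weights <- seq_len(ncol(counts))
    tot <- rowSums(counts)
    if (any(tot == 0))
        stop("expression score undefined for all-zero count vectors")
    as.numeric(counts %*% weights) / tot
}

#' Reversed repression scale
#'
#' Converts an expression score to a repression score,
#' \eqn{r = e_{max} + 1 - e}, so that strong repression (low GFP) maps to
#' high values.
#'
#' @param e expression score(s) in \code{[1, eMax]}.
#' @param eMax the maximum expression score (number of bins, default 13).
#' @return Repression score(s) in \code{[1, eMax]}.
#' @examples
#' repressionScore(13)  # 1
#' repressionScore(1)   # 13
#' @export
repressionScore <- function(e, eMax = 13) {
    if (any(e < 1 - 1e-9 | e > eMax + 1e-9))
        stop("expression scores must lie in [1, eMax]")
    eMax + 1 - e
}

#' Filter genotypes across replicates and compute repression scores
#'
#' Applies the replicate quality filters: a genotype is retained only if it
#' is present (has reads) in every replicate, has at least \code{minReads}
#' reads in every replicate, and the coefficient of variation of its
#' per-replicate repression scores is at most \code{maxCV}. Per-replicate
#' expression and repression scores and the replicate-mean repression are
#' computed for the survivors.
#'
#' By default \code{minReads} applies to a genotype's total reads summed over
#' bins within each replicate; \code{perBin = TRUE} instead demands
#' \code{minReads} in every single bin.
#'
#' @param table a \linkS4class{BinCountTable} with >= 2 replicates.
#' @param minReads minimum reads per replicate (default 30).
#' @param maxCV maximum coefficient of variation of per-replicate repression
#'   (default 0.5).
#' @param perBin if \code{TRUE}, apply \code{minReads} per bin.
#' @return A \linkS4class{ScoreTable}. Removal reasons are recorded in
#'   \code{metadata(result)$removed}; the surviving-count funnel in
#'   \code{metadata(result)$funnel}.
#' @examples
#' sp <- genotypeSpace(2, context = NA)
#' tr <- makeHoCLandscape(sp, seed = 1)
#' bc <- simulateSortSeq(tr, sortSeqConfig(seed = 1, cellsPerGenotype = 50L))
#' st <- filterVariants(bc)
#' @export
filterVariants <- function(table, minReads = 30, maxCV = 0.5, perBin = FALSE) {
    as_ <- SummarizedExperiment::assays(table)
    K <- length(as_)
    if (K < 2L) stop("need at least 2 replicates")
    g <- rownames(table)
    w <- SummarizedExperiment::colData(table)$bin
    eMax <- max(w)
    tot <- vapply(as_, rowSums, numeric(length(g)))      # n x K
    present <- rowSums(tot > 0) == K
    if (perBin) {
        okDepth <- Reduce(`&`, lapply(as_, function(a)
            rowSums(a >= minReads) == ncol(a)))
    } else {
        okDepth <- rowSums(tot >= minReads) == K
    }
    candidate <- present & okDepth
    rmat <- matrix(NA_real_, length(g), K,
                   dimnames = list(g, names(as_)))
    for (k in seq_len(K)) {
        idx <- which(candidate)
        a <- as_[[k]][idx, , drop = FALSE]
        rmat[idx, k] <- repressionScore(expressionScore(a, w), eMax)
    }
    meanR <- rowMeans(rmat)
    sdR <- apply(rmat, 1L, stats::sd)
    cv <- ifelse(meanR > 0, sdR / meanR, Inf)
    keep <- candidate & !is.na(cv) & cv <= maxCV

    reason <- rep(NA_character_, length(g))
    reason[!present] <- "absent"
    reason[present & !okDepth] <- "min_reads"
    reason[candidate & !keep] <- "max_cv"
    removed <- S4Vectors::DataFrame(genotype = g[!keep],
                                    reason = reason[!keep])
    funnel <- c(input = length(g), present = sum(present),
                depth = sum(candidate), cv = sum(keep))

    df <- S4Vectors::DataFrame(genotype = g[keep], row.names = g[keep])
    for (k in seq_len(K)) df[[paste0("e_", names(as_)[k])]] <-
        eMax + 1 - rmat[keep, k]
    for (k in seq_len(K)) df[[paste0("r_", names(as_)[k])]] <- rmat[keep, k]
    for (k in seq_len(K)) df[[paste0("reads_", names(as_)[k])]] <-
        as.integer(tot[keep, k])
    df$meanR <- meanR[keep]
    df$cv <- cv[keep]
    df$S <- NA_real_
    df$tau <- NA_real_
    out <- new("ScoreTable", df)
    metadata(out) <- list(space = metadata(table)$space,
                          eMax = eMax, nReplicates = K,
                          minReads = minReads, maxCV = maxCV, perBin = perBin,
                          removed = removed, funnel = funnel,
                          wildtype = NA_character_)
    if (nrow(out) == 0L)
        warning("no genotypes survive the filters")
    message(sprintf(
        "filter funnel: %d input -> %d present in all replicates -> %d with >= %s reads -> %d with CV <= %s",
        funnel["input"], funnel["present"], funnel["depth"],
        format(minReads), funnel["cv"], format(maxCV)))
    out
}

#' Normalise repression scores by the wild type
#'
#' Divides the replicate-mean repression of every genotype by that of the
#' wild-type genotype, so the wild type scores exactly 1 and scores are
#' expressed in wild-type units. The per-genotype noise \code{tau} is the
#' standard deviation of the per-replicate repression scores on the same
#' normalised scale.
#'
#' @param scores a \linkS4class{ScoreTable} from \code{\link{filterVariants}}.
#' @param wildtype the wild-type genotype string (variable positions only).
#' @return The \linkS4class{ScoreTable} with \code{S} and \code{tau} filled.
#' @export
normalizeByWildtype <- function(scores, wildtype) {
    i <- match(wildtype, scores$genotype)
    if (is.na(i)) {
        rem <- metadata(scores)$removed
        j <- match(wildtype, rem$genotype)
        if (!is.na(j))
            stop("wild type '", wildtype, "' was removed by the '",
                 rem$reason[j], "' filter")
        stop("wild type '", wildtype, "' is not present in the count table")
    }
    rwt <- scores$meanR[i]
    if (!is.finite(rwt) || rwt <= 0)
        stop("wild-type repression is not positive")
    scores$S <- scores$meanR / rwt
    rcols <- grep("^r_rep", colnames(scores), value = TRUE)
    rmat <- as.matrix(as.data.frame(scores[, rcols])) / rwt
    scores$tau <- apply(rmat, 1L, stats::sd)
    md <- metadata(scores)
    md$wildtype <- wildtype
    metadata(scores) <- md
    scores
}

#' Nucleotide frequency matrix and information content
#'
#' Counts the frequency of each nucleotide at each variable position of a
#' genotype set (e.g. the strongest binders) and computes the per-position
#' information content in bits, \eqn{2 - H}, where \eqn{H} is the Shannon
#' entropy (log2) of the position's frequency column. Conserved positions
#' approach 2 bits; positions with all four bases equally frequent have 0.
#'
#' @param genotypes non-empty character vector, uniform length.
#' @return List with \code{frequencies} (4 x L matrix, columns summing to 1)
#'   and \code{information} (numeric length L, bits).
#' @examples
#' frequencyMatrix(c("AC", "AG"))$information  # 2 bits, 1 bit
#' @export
frequencyMatrix <- function(genotypes) {
    if (!length(genotypes)) stop("empty genotype set")
    L <- nchar(genotypes[1L])
    m <- .alleleIndexMatrix(genotypes, L)
    freq <- vapply(seq_len(L), function(p)
        tabulate(m[, p] + 1L, nbins = 4L) / length(genotypes),
        numeric(4L))
    rownames(freq) <- DNA_ALPHABET
    ent <- apply(freq, 2L, function(f) {
        f <- f[f > 0]
        -sum(f * log2(f))
    })
    list(frequencies = freq, information = 2 - ent)
}
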