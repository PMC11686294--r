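# Genotype encoding and Hamming-graph machinery.
#
# Genotypes are strings over {A,C,G,T}. Internally each genotype maps to a
# base-4 integer code (position 1 is the least-significant digit), which makes
# neighbor generation and edge matching O(3 L n) with vectorised arithmetic.
# Codes stay below 2^31 for L <= 15, which covers any realistic library.

.alleleIndexMatrix <- function(genotypes, L) {
    if (!length(genotypes)) return(matrix(integer(0), 0, L))
    chars <- strsplit(genotypes, "", fixed = TRUE)
    if (any(lengths(chars) != L))
        stop("all genotypes must have length ", L)
    idx <- match(unlist(chars, use.names = FALSE), DNA_ALPHABET) - 1L
    if (anyNA(idx))
        stop("genotypes contain characters outside A,C,G,T")
    matrix(idx, ncol = L, byrow = TRUE)
}

.encodeGenotypes <- function(genotypes, L) {
    m <- .alleleIndexMatrix(genotypes, L)
    as.numeric(m %*% 4^(seq_len(L) - 1))
}

.decodeGenotypes <- function(codes, L) {
    cols <- lapply(seq_len(L) - 1L, function(p)
        DNA_ALPHABET[(codes %/% 4^p) %% 4 + 1L])
    do.call(paste0, cols)
}

#' Enumerate all genotypes of a space
#'
#' Returns all \eqn{4^L} genotypes of a \linkS4class{GenotypeSpace}, in
#' base-4 code order.
#'
#' @param space a \linkS4class{GenotypeSpace}.
#' @return Character vector of length \eqn{4^L}.
#' @examples
#' enumerateGenotypes(genotypeSpace(2, context = NA))
#' @export
enumerateGenotypes <- function(space) {
    L <- space@length
    if (4^L > 2^24)
        stop("space too large to enumerate (L = ", L, ")")
    .decodeGenotypes(seq_len(4^L) - 1, L)
}

# Undirected Hamming-distance-1 edge list over an observed genotype set.
# Returns an m x 2 integer matrix of node indices with col1 < col2.
.hammingEdges <- function(genotypes, L) {
    n <- length(genotypes)
    if (n < 2L) return(matrix(integer(0), 0, 2))
    m <- .alleleIndexMatrix(genotypes, L)
    codes <- as.numeric(m %*% 4^(seq_len(L) - 1))
    from <- to <- vector("list", 3L * L)
    k <- 0L
    for (p in seq_len(L)) {
        pw <- 4^(p - 1)
        cur <- m[, p]
        for (d in 1:3) {
            k <- k + 1L
            ncode <- codes + (((cur + d) %% 4) - cur) * pw
            j <- match(ncode, codes)
            i <- seq_len(n)
            keep <- !is.na(j) & i < j
            from[[k]] <- i[keep]; to[[k]] <- j[keep]
        }
    }
    cbind(unlist(from, use.names = FALSE), unlist(to, use.names = FALSE))
}

#' Embed variant genotypes in their fixed sequence context
#'
#' Substitutes the variable characters of each genotype into the \code{N}
#' placeholders of the space's context sequence.
#'
#' @param space a \linkS4class{GenotypeSpace} with a context.
#' @param genotypes character vector of variant strings (length L each).
#' @return Character vector of full-context sequences.
#' @examples
#' fullContextSequence(genotypeSpace(8), "ACGTACGT")
#' @export
fullContextSequence <- function(space, genotypes) {
    if (is.na(space@context))
        stop("space has no context sequence")
    ctx <- strsplit(space@context, "")[[1]]
    varPos <- which(ctx == "N")
    m <- .alleleIndexMatrix(genotypes, space@length)
    vapply(seq_along(genotypes), function(i) {
        s <- ctx
        s[varPos] <- DNA_ALPHABET[m[i, ] + 1L]
        paste(s, collapse = "")
    }, character(1))
}

#' Pairwise Hamming-distance distribution of a genotype set
#'
#' Computes Hamming distances over the variable positions for every unordered
#' pair of genotypes, as used to ask whether peak genotypes cluster in
#' sequence space. For a complete space over \eqn{L} positions the mean
#' pairwise distance is \eqn{3L/4} (pair including self-pairs excluded).
#'
#' @param genotypes character vector (>= 2, uniform length).
#' @return List with \code{distances} (integer vector, one per unordered
#'   pair), \code{histogram} (counts indexed 0..L) and \code{mean}.
#' @examples
#' pairwiseDistanceDistribution(c("AAAA", "AAAT", "TTTT"))$mean
#' @export
pairwiseDistanceDistribution <- function(genotypes) {
    n <- length(genotypes)
    if (n < 2L) stop("need at least 2 genotypes")
    L <- nchar(genotypes[1L])
    m <- .alleleIndexMatrix(genotypes, L)
    d <- matrix(0L, n, n)
    for (p in seq_len(L))
        d <- d + outer(m[, p], m[, p], "!=")
    dv <- d[upper.tri(d)]
    hist <- tabulate(dv + 1L, nbins = L + 1L)
    names(hist) <- 0:L
    list(distances = as.integer(dv), histogram = hist, mean = mean(dv))
}
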