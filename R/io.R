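# Readers and writers for the on-disk TSV dialects. Genotypes are stored as
# the variable characters only; the fixed context lives in the space
# definition. Files may carry a "# config=<hash>" comment line so artifacts
# from different pipeline configurations cannot be mixed silently.

.writeStamped <- function(df, path, hash = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(hash)) writeLines(paste0("# config=", hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.readStamped <- function(path, expectedHash = NULL) {
    first <- readLines(path, n = 1L)
    hash <- if (startsWith(first, "# config=")) sub("^# config=", "", first)
            else NULL
    if (!is.null(expectedHash) && !is.null(hash) &&
        !identical(hash, expectedHash))
        stop("config hash mismatch: file '", path, "' carries ", hash,
             ", expected ", expectedHash)
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE)
    attr(df, "configHash") <- hash
    df
}

#' Write and read sort-seq bin-count tables
#'
#' The TSV dialect has columns \code{genotype}, \code{replicate}, and
#' \code{bin_01} ... \code{bin_NN} (integer read counts), one row per
#' genotype and replicate.
#'
#' @param table a \linkS4class{BinCountTable}.
#' @param path file path.
#' @param hash optional config hash stamped into a comment header.
#' @return \code{writeBinCounts}: the path, invisibly. \code{readBinCounts}:
#'   a \linkS4class{BinCountTable}.
#' @export
writeBinCounts <- function(table, path, hash = NULL) {
    as_ <- SummarizedExperiment::assays(table)
    rows <- lapply(names(as_), function(nm) {
        a <- as_[[nm]]
        df <- data.frame(genotype = rownames(table), replicate = nm,
                         a, check.names = FALSE)
        colnames(df)[-(1:2)] <- colnames(table)
        df
    })
    .writeStamped(do.call(rbind, rows), path, hash)
}

#' @rdname writeBinCounts
#' @param space a \linkS4class{GenotypeSpace} for the genotypes in the file
#'   (default: inferred from the genotype length, without context).
#' @param expectedHash if given, reading fails when the file carries a
#'   different config hash.
#' @export
readBinCounts <- function(path, space = NULL, expectedHash = NULL) {
    df <- .readStamped(path, expectedHash)
    need <- c("genotype", "replicate")
    if (!all(need %in% colnames(df)))
        stop("missing required columns: ",
             paste(setdiff(need, colnames(df)), collapse = ", "))
    binCols <- grep("^bin_", colnames(df), value = TRUE)
    if (length(binCols) < 2L)
        stop("no bin_* count columns found")
    cnt <- as.matrix(df[binCols])
    bad <- which(rowSums(is.na(cnt) | cnt < 0 | cnt != floor(cnt)) > 0)
    if (length(bad))
        stop("invalid (negative or non-integer) counts at data row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "))
    badG <- which(!grepl("^[ACGT]+$", df$genotype))
    if (length(badG))
        stop("non-ACGT genotype characters at data row(s) ",
             paste(utils::head(badG, 5L), collapse = ", "))
    L <- nchar(df$genotype[1L])
    if (is.null(space)) space <- genotypeSpace(L, context = NA)
    reps <- unique(df$replicate)
    gts <- unique(df$genotype)
    assayList <- lapply(reps, function(r) {
        sub <- df[df$replicate == r, , drop = FALSE]
        i <- match(gts, sub$genotype)
        if (anyNA(i)) stop("replicate '", r, "' is missing genotypes")
        m <- as.matrix(sub[i, binCols])
        storage.mode(m) <- "integer"
        rownames(m) <- gts
        colnames(m) <- NULL
        m
    })
    names(assayList) <- reps
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assayList,
        colData = S4Vectors::DataFrame(bin = seq_along(binCols),
                                       row.names = binCols))
    out <- new("BinCountTable", se)
    metadata(out) <- list(space = space,
                          configHash = attr(df, "configHash"))
    out
}

#' Write and read ground-truth landscapes
#'
#' TSV with columns \code{genotype} and \code{true_repression}.
#'
#' @param truth a \linkS4class{GroundTruthLandscape}.
#' @param path file path.
#' @param hash optional config hash.
#' @return The path (writers) or a named numeric vector of true repression
#'   values (reader).
#' @export
writeTruth <- function(truth, path, hash = NULL) {
    .writeStamped(data.frame(genotype = truth@genotype,
                             true_repression = truth@trueRepression),
                  path, hash)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path, expectedHash = NULL) {
    df <- .readStamped(path, expectedHash)
    stats::setNames(df$true_repression, df$genotype)
}

#' @rdname writeTruth
#' @param space the \linkS4class{GenotypeSpace} providing the fixed context.
#' @export
writeTruthFasta <- function(truth, path, space = truth@space) {
    seqs <- Biostrings::DNAStringSet(
        fullContextSequence(space, truth@genotype))
    names(seqs) <- truth@genotype
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Write and read score tables
#'
#' TSV with columns \code{genotype}, \code{S}, \code{cv}, \code{tau},
#' \code{meanR} and the per-replicate \code{e_rep*}, \code{r_rep*},
#' \code{reads_rep*} columns.
#'
#' @param scores a \linkS4class{ScoreTable}.
#' @param path file path.
#' @param hash optional config hash.
#' @export
writeScoreTable <- function(scores, path, hash = NULL) {
    .writeStamped(as.data.frame(scores), path, hash)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path, expectedHash = NULL) {
    df <- .readStamped(path, expectedHash)
    out <- new("ScoreTable", S4Vectors::DataFrame(df, row.names = df$genotype))
    metadata(out) <- list(configHash = attr(df, "configHash"))
    out
}

#' Export a landscape as node and edge tables (and optionally GraphML)
#'
#' Writes \code{<prefix>_nodes.tsv} (genotype, S, tau, is_peak, plateau_id,
#' rel_connectivity) and \code{<prefix>_edges.tsv} (src, dst, direction with
#' \code{up} meaning src -> dst uphill and \code{neutral} for ties or
#' indistinguishable pairs), plus \code{<prefix>.graphml} when
#' \code{graphml = TRUE}.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param prefix path prefix for the output files.
#' @param graphml also write a GraphML file (default FALSE).
#' @param hash optional config hash.
#' @return Character vector of the files written.
#' @export
writeLandscape <- function(landscape, prefix, graphml = FALSE, hash = NULL) {
    nodes <- data.frame(genotype = landscape@genotype,
                        S = landscape@score, tau = landscape@tau,
                        is_peak = landscape@isPeak,
                        plateau_id = landscape@plateauId,
                        rel_connectivity = landscape@relConnectivity)
    e <- landscape@edges; st <- landscape@edgeState
    src <- ifelse(st == 2L, e[, 2L], e[, 1L])
    dst <- ifelse(st == 2L, e[, 1L], e[, 2L])
    edges <- data.frame(src = landscape@genotype[src],
                        dst = landscape@genotype[dst],
                        direction = c("neutral", "up", "up")[st + 1L])
    files <- c(paste0(prefix, "_nodes.tsv"), paste0(prefix, "_edges.tsv"))
    .writeStamped(nodes, files[1L], hash)
    .writeStamped(edges, files[2L], hash)
    if (graphml) {
        g <- .undirectedIgraph(landscape)
        igraph::V(g)$name <- landscape@genotype
        igraph::V(g)$score <- landscape@score
        igraph::V(g)$is_peak <- landscape@isPeak
        f3 <- paste0(prefix, ".graphml")
        igraph::write_graph(g, f3, format = "graphml")
        files <- c(files, f3)
    }
    invisible(files)
}

#' @rdname writeLandscape
#' @param nodesPath path to a \code{*_nodes.tsv} file.
#' @param space the \linkS4class{GenotypeSpace}; inferred when NULL.
#' @param expectedHash optional config hash check.
#' @export
readLandscape <- function(nodesPath, space = NULL, expectedHash = NULL) {
    df <- .readStamped(nodesPath, expectedHash)
    if (is.null(space))
        space <- genotypeSpace(nchar(df$genotype[1L]), context = NA)
    ls <- .makeLandscape(space, df$genotype, df$S,
                         if ("tau" %in% colnames(df)) df$tau else NULL)
    ls
}
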