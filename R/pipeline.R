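# End-to-end pipeline: simulate -> score -> landscape -> topography ->
# evolve, with every stage seeded from the global seed plus its stage label,
# every artifact stamped with the config hash, and a machine-readable run
# manifest. Identical configs produce byte-identical outputs.

.defaultPipelineConfig <- function() {
    list(
        seed = 1L,
        stages = c("simulate", "score", "landscape", "topography", "evolve"),
        space = list(length = 4L),
        simulate = list(model = "NK", K = 1L, cellsPerGenotype = 50L,
                        nReplicates = 3L, cellNoiseSd = 0.8,
                        replicateNoiseSd = 0.9),
        score = list(minReads = 30, maxCV = 0.5, perBin = FALSE,
                     wildtype = NULL),
        landscape = list(epsilon = 0, noiseScale = NA, shuffles = 100L),
        topography = list(highPeakThreshold = 1, pca = TRUE),
        evolve = list(mode = "uniform", walksPerStart = 10L,
                      starts = "sample:50", N = 1e8, maxSteps = 200L)
    )
}

.mergeConfig <- function(base, user) {
    for (nm in names(user)) {
        if (is.list(base[[nm]]) && is.list(user[[nm]]))
            base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
        else base[[nm]] <- user[[nm]]
    }
    base
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unspecified fields fall back to package defaults; the returned list
#' round-trips losslessly through \code{yaml::write_yaml}.
#'
#' @param path path to a YAML (\code{.yml}/\code{.yaml}) or JSON file, or a
#'   configuration list.
#' @return A complete configuration list.
#' @export
readPipelineConfig <- function(path) {
    user <- if (is.list(path)) path
            else if (grepl("\\.json$", path))
                jsonlite::read_json(path, simplifyVector = TRUE)
            else yaml::read_yaml(path)
    .mergeConfig(.defaultPipelineConfig(), user)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order
#' simulate -> score -> landscape -> topography -> evolve, writing every
#' intermediate artifact into \code{outDir} together with a
#' \code{manifest.json} recording the stages run, the derived per-stage
#' seeds, the configuration and its hash, and the package version. Stage
#' failures abort with the stage name.
#'
#' @param config a configuration list or a path accepted by
#'   \code{\link{readPipelineConfig}}.
#' @param outDir output directory (created if missing).
#' @return The output directory, invisibly; the manifest lists the artifacts.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("sortscape_run_")) {
    cfg <- readPipelineConfig(config)
    hash <- .configHash(cfg)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stages <- cfg$stages
    manifest <- list(package = "SortScape",
                     version = as.character(utils::packageVersion("SortScape")),
                     configHash = hash, config = cfg,
                     stages = list(), artifacts = character(0))
    truth <- NULL; counts <- NULL; scores <- NULL; ls <- NULL

    runStage <- function(name, fn) {
        if (!name %in% stages) return(invisible(NULL))
        res <- tryCatch(fn(), error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        manifest$stages[[name]] <<- list(seed = .stageSeed(cfg$seed, name))
        res
    }

    runStage("simulate", function() {
        sp <- genotypeSpace(cfg$space$length,
                            context = cfg$space$context %||% NA_character_)
        seed <- .stageSeed(cfg$seed, "simulate")
        truth <<- switch(cfg$simulate$model,
            additive = makeAdditiveLandscape(sp, seed = seed),
            NK = makeNKLandscape(sp, K = cfg$simulate$K, seed = seed),
            HoC = makeHoCLandscape(sp, seed = seed),
            stop("unknown model '", cfg$simulate$model, "'"))
        sim <- sortSeqConfig(
            cellsPerGenotype = cfg$simulate$cellsPerGenotype,
            nReplicates = cfg$simulate$nReplicates,
            cellNoiseSd = cfg$simulate$cellNoiseSd,
            replicateNoiseSd = cfg$simulate$replicateNoiseSd,
            seed = seed)
        counts <<- simulateSortSeq(truth, sim)
        writeTruth(truth, file.path(outDir, "truth.tsv"), hash)
        writeBinCounts(counts, file.path(outDir, "counts.tsv"), hash)
        manifest$artifacts <<- c(manifest$artifacts, "truth.tsv", "counts.tsv")
    })

    runStage("score", function() {
        if (is.null(counts)) stop("no count table (enable the simulate stage)")
        st <- filterVariants(counts, minReads = cfg$score$minReads,
                             maxCV = cfg$score$maxCV,
                             perBin = isTRUE(cfg$score$perBin))
        wt <- cfg$score$wildtype
        if (is.null(wt)) {
            # reference genotype: strongest surviving true repressor
            keep <- match(st$genotype, truth@genotype)
            wt <- st$genotype[which.max(truth@trueRepression[keep])]
        }
        scores <<- normalizeByWildtype(st, wt)
        writeScoreTable(scores, file.path(outDir, "scores.tsv"), hash)
        manifest$artifacts <<- c(manifest$artifacts, "scores.tsv")
    })

    runStage("landscape", function() {
        if (is.null(scores)) stop("no score table (enable the score stage)")
        ls0 <- buildNetwork(scores, epsilon = cfg$landscape$epsilon)
        ls0 <- giantComponent(ls0)
        if (!is.na(cfg$landscape$noiseScale))
            ls0 <- applyNoiseModel(ls0, scale = cfg$landscape$noiseScale)
        ls <<- ls0
        writeLandscape(ls0, file.path(outDir, "landscape"), hash = hash)
        out <- list(nodes = length(ls0@genotype),
                    edges = nrow(ls0@edges),
                    peaks = sum(ls0@isPeak))
        if (cfg$landscape$shuffles > 0) {
            sh <- shuffleNull(ls0, cfg$landscape$shuffles,
                              seed = .stageSeed(cfg$seed, "shuffle"))
            out$shuffleNull <- sh[c("mean", "sd", "upper95")]
        }
        jsonlite::write_json(out, file.path(outDir, "landscape_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        manifest$artifacts <<- c(manifest$artifacts, "landscape_nodes.tsv",
                                 "landscape_edges.tsv",
                                 "landscape_summary.json")
    })

    runStage("topography", function() {
        if (is.null(ls)) stop("no landscape (enable the landscape stage)")
        thr <- cfg$topography$highPeakThreshold
        pk <- findPeaks(ls)
        highPk <- ls@genotype[ls@isPeak & ls@score > thr]
        basins <- lapply(highPk, function(p) basinOfAttraction(ls, p))
        basinDf <- data.frame(
            peak = highPk,
            size = vapply(basins, function(b) b$size, numeric(1)),
            fraction = vapply(basins, function(b) b$fraction, numeric(1)))
        .writeStamped(basinDf, file.path(outDir, "basins.tsv"), hash)
        sqr <- enumerateSquares(ls)
        jsonlite::write_json(
            list(peaks = pk$peakCount, plateaus = pk$plateauCount,
                 highPeaks = length(highPk),
                 epistasis = as.list(sqr$proportions),
                 nSquares = sqr$nSquares),
            file.path(outDir, "topography_summary.json"),
            auto_unbox = TRUE, digits = NA)
        if (isTRUE(cfg$topography$pca) && length(ls@genotype) >= 2) {
            pca <- onehotPCA(ls@genotype, ls@score)
            .writeStamped(data.frame(genotype = ls@genotype,
                                     round(pca$coordinates[, 1:2], 6)),
                          file.path(outDir, "pca.tsv"), hash)
        }
        manifest$artifacts <<- c(manifest$artifacts, "basins.tsv",
                                 "topography_summary.json")
    })

    runStage("evolve", function() {
        if (is.null(ls)) stop("no landscape (enable the landscape stage)")
        ev <- cfg$evolve
        seed <- .stageSeed(cfg$seed, "evolve")
        starts <- if (identical(ev$starts, "all-nonpeak")) NULL
        else {
            k <- as.integer(sub("^sample:", "", ev$starts))
            nonPeak <- ls@genotype[!ls@isPeak]
            .withSeed(seed, sample(nonPeak, min(k, length(nonPeak))))
        }
        walks <- runWalks(ls, mode = ev$mode, starts = starts,
                          walksPerStart = ev$walksPerStart, seed = seed,
                          N = ev$N, maxSteps = ev$maxSteps,
                          highThreshold = cfg$topography$highPeakThreshold)
        sm <- walkSummary(walks, ls, cfg$topography$highPeakThreshold)
        walkDf <- data.frame(
            start = vapply(walks, function(w) w@start, character(1)),
            endpoint = vapply(walks, function(w) w@endpoint, character(1)),
            steps = vapply(walks, function(w) w@steps, integer(1)),
            ended_on_high_peak = vapply(walks, function(w)
                w@endpointIsHighPeak, logical(1)))
        .writeStamped(walkDf, file.path(outDir, "walks.tsv"), hash)
        jsonlite::write_json(
            list(nWalks = sm$nWalks, fractionHigh = sm$fractionHigh,
                 meanSteps = sm$meanSteps),
            file.path(outDir, "walk_summary.json"),
            auto_unbox = TRUE, digits = NA)
        manifest$artifacts <<- c(manifest$artifacts, "walks.tsv",
                                 "walk_summary.json")
    })

    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(outDir)
}
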