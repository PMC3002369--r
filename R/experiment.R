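#' Run a full consensus clustering experiment
#'
#' The orchestrated pipeline: optional preprocessing (transposition,
#' variance filtering, unitisation), consensus clustering for the full
#' factorial of algorithms x cluster numbers, per-k merging when two or
#' more algorithms are configured, robustness of every consensus matrix
#' against its own reference and of every merge against each source's
#' reference, and delta-K profiles per algorithm plus the merge. All
#' randomness derives from `seed`; a rerun with an identical configuration
#' reproduces the bundle exactly. A failing (algorithm, k) cell is logged
#' and skipped; the bundle then reports partial completion in its log.
#'
#' @param data expression matrix (anything [asExpressionMatrix()]
#'   accepts).
#' @param algorithms list of [AlgorithmSpec-class]; default the three
#'   built-ins (hierarchical average-linkage, k-means, pam).
#' @param kRange integer vector of cluster numbers; default 2:7.
#' @param iterations resampling iterations per cell; default 100.
#' @param proportion row subsampling fraction; default 0.8.
#' @param seed master seed.
#' @param weights optional merge weights, one per algorithm.
#' @param transpose transpose the matrix first (e.g. to cluster
#'   conditions/patients)?
#' @param varianceFilterN optional: keep only the N most variable rows.
#' @param unitiseMethod optional: `"norm"` or `"standardise"` row scaling.
#' @param outDir optional output directory; when given, all matrices,
#'   reports, tables, the configuration (JSON) and the log are written
#'   there.
#' @param keepAssignments retain per-iteration assignments in each
#'   [ConsensusResult-class].
#' @return a [ConsensusExperiment-class].
#' @examples
#' sim <- simulateProfiles(nPerProfile = 10, spikeCounts = c(2, 2, 2, 2),
#'                         seed = 11)
#' ex <- runConsensusExperiment(sim,
#'     algorithms = list(algorithmSpec("pam"), algorithmSpec("kmeans")),
#'     kRange = 3:5, iterations = 20, seed = 11)
#' estimateK(deltaKProfiles(ex)$merge)
#' @export
runConsensusExperiment <- function(data,
                                   algorithms = list(
                                       algorithmSpec("hierarchical"),
                                       algorithmSpec("kmeans"),
                                       algorithmSpec("pam")),
                                   kRange = 2:7,
                                   iterations = 100L,
                                   proportion = 0.8,
                                   seed = 1L,
                                   weights = NULL,
                                   transpose = FALSE,
                                   varianceFilterN = NULL,
                                   unitiseMethod = NULL,
                                   outDir = NULL,
                                   keepAssignments = FALSE) {
    x <- asExpressionMatrix(data)
    logLines <- character(0)
    note <- function(...) {
        line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
        logLines <<- c(logLines, line)
        invisible(line)
    }
    note("experiment start: ", nrow(x), " x ", ncol(x), " matrix, seed ",
         seed)

    if (isTRUE(transpose)) {
        x <- transposeMatrix(x)
        note("transposed to ", nrow(x), " x ", ncol(x))
    }
    if (!is.null(varianceFilterN)) {
        x <- varianceFilter(x, varianceFilterN)
        note("variance filter kept ", nrow(x), " rows")
    }
    if (!is.null(unitiseMethod)) {
        x <- unitise(x, unitiseMethod)
        note("unitised rows (", unitiseMethod, ")")
    }

    algNames <- vapply(algorithms, function(s) s@algorithm, character(1))
    if (anyDuplicated(algNames))
        algNames <- make.unique(algNames, sep = ".")
    kRange <- sort(as.integer(kRange))

    consensus <- list()
    set.seed(seed)
    cellSeeds <- matrix(sample.int(2147483646L,
                                   length(kRange) * length(algorithms)),
                        nrow = length(kRange))
    for (ki in seq_along(kRange)) {
        for (ai in seq_along(algorithms)) {
            cellName <- paste0(algNames[ai], ".k", kRange[ki])
            t0 <- Sys.time()
            res <- tryCatch(
                consensusCluster(x, algorithms[[ai]], k = kRange[ki],
                                 iterations = iterations,
                                 proportion = proportion,
                                 seed = cellSeeds[ki, ai],
                                 keepAssignments = keepAssignments),
                error = function(e) e)
            if (inherits(res, "error")) {
                note("FAILED ", cellName, ": ", conditionMessage(res))
            } else {
                consensus[[cellName]] <- res
                note(cellName, " done in ",
                     round(as.numeric(Sys.time() - t0, units = "secs"), 2),
                     " s (cell seed ", cellSeeds[ki, ai], ")")
            }
        }
    }

    merges <- list()
    if (length(algorithms) >= 2L) {
        for (k in kRange) {
            cells <- consensus[paste0(algNames, ".k", k)]
            cells <- cells[!vapply(cells, is.null, logical(1))]
            if (length(cells) >= 2L) {
                merges[[paste0("k", k)]] <-
                    mergeConsensus(unname(cells), weights = weights)
            } else {
                note("merge skipped at k = ", k,
                     ": fewer than two completed cells")
            }
        }
    } else {
        note("single algorithm configured; no merge produced")
    }

    robustness <- list()
    for (nm in names(consensus)) {
        res <- consensus[[nm]]
        robustness[[paste0(nm, ".self")]] <- suppressWarnings(
            robustnessReport(res, referenceClustering(res), source = nm))
    }
    for (km in names(merges)) {
        k <- as.integer(sub("^k", "", km))
        for (ai in seq_along(algorithms)) {
            cellName <- paste0(algNames[ai], ".k", k)
            if (is.null(consensus[[cellName]])) next
            ref <- referenceClustering(consensus[[cellName]])
            robustness[[paste0("merge.k", k, ".on.", algNames[ai])]] <-
                suppressWarnings(robustnessReport(merges[[km]], ref,
                                 source = "merge"))
        }
    }

    deltaKList <- list()
    if (length(kRange) >= 2L) {
        for (ai in seq_along(algNames)) {
            cells <- consensus[paste0(algNames[ai], ".k", kRange)]
            ok <- !vapply(cells, is.null, logical(1))
            if (sum(ok) >= 2L) {
                aucs <- vapply(cells[ok], consensusAUC, numeric(1))
                deltaKList[[algNames[ai]]] <-
                    deltaK(aucs, k = kRange[ok], source = algNames[ai])
            }
        }
        if (length(merges) >= 2L) {
            mk <- as.integer(sub("^k", "", names(merges)))
            aucs <- vapply(merges, consensusAUC, numeric(1))
            deltaKList[["merge"]] <- deltaK(aucs, k = mk, source = "merge")
        }
    }

    config <- list(
        algorithms = lapply(algorithms, function(s)
            list(algorithm = s@algorithm, distance = s@distance,
                 linkage = s@linkage, params = s@params)),
        kRange = kRange, iterations = iterations, proportion = proportion,
        seed = seed, weights = weights, transpose = transpose,
        varianceFilterN = varianceFilterN, unitiseMethod = unitiseMethod,
        completedCells = names(consensus),
        packageVersion = as.character(utils::packageVersion("consensusMerge"))
    )
    note("experiment complete: ", length(consensus), " consensus cells, ",
         length(merges), " merges")

    bundle <- new("ConsensusExperiment", consensus = consensus,
                  merges = merges, robustness = robustness,
                  deltaK = deltaKList, config = config, log = logLines)
    if (!is.null(outDir))
        .writeBundle(bundle, outDir)
    bundle
}

.writeBundle <- function(bundle, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(bundle@consensus))
        writeConsensusMatrix(bundle@consensus[[nm]],
                             file.path(outDir, paste0(nm, ".consensus.tsv")))
    for (nm in names(bundle@merges))
        writeConsensusMatrix(bundle@merges[[nm]],
                             file.path(outDir, paste0("merge.", nm, ".tsv")))
    for (nm in names(bundle@robustness))
        writeRobustnessReport(bundle@robustness[[nm]],
                              file.path(outDir,
                                        paste0(nm, ".robustness.tsv")))
    if (length(bundle@deltaK))
        writeDeltaKTable(bundle@deltaK, file.path(outDir, "delta_k.tsv"))
    jsonlite::write_json(bundle@config, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(bundle@log, file.path(outDir, "run.log"))
    invisible(outDir)
}

#' @describeIn ConsensusExperiment per-cell consensus results.
#' @param x a `ConsensusExperiment`.
#' @export
consensusResults <- function(x) x@consensus

#' @describeIn ConsensusExperiment per-k merged matrices.
#' @export
mergeResults <- function(x) x@merges

#' @describeIn ConsensusExperiment all robustness reports.
#' @export
robustnessReports <- function(x) x@robustness

#' @describeIn ConsensusExperiment delta-K profiles per source.
#' @export
deltaKProfiles <- function(x) x@deltaK

#' @describeIn ConsensusExperiment the run log.
#' @export
experimentLog <- function(x) x@log

setMethod("show", "ConsensusExperiment", function(object) {
    cat("ConsensusExperiment:", length(object@consensus),
        "consensus cells,", length(object@merges), "merges,",
        length(object@robustness), "robustness reports\n")
    if (length(object@deltaK)) {
        cat("  estimated k by source:\n")
        for (nm in names(object@deltaK)) {
            est <- suppressWarnings(estimateK(object@deltaK[[nm]]))
            cat("    ", nm, ": ", est, " (", attr(est, "flag"), ")\n",
                sep = "")
        }
    }
})
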