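.detectSep <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("\t", first)) "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' Reads a CSV or TSV file with a header row and the feature identifiers
#' in the first column. The delimiter is auto-detected from the first line
#' (tab wins over comma) unless forced. Duplicate identifiers, non-numeric
#' cells and ragged rows are reported as errors naming the offending
#' row or column.
#'
#' @param path file path.
#' @param sep optional delimiter, `","` or `"\t"`; default auto-detect.
#' @return a numeric features x conditions matrix.
#' @export
readExpressionMatrix <- function(path, sep = NULL) {
    if (!file.exists(path))
        stop("no such file: ", path)
    if (is.null(sep))
        sep <- .detectSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character", quote = "\"",
                            comment.char = "")
    if (ncol(df) < 2L)
        stop("expected a feature-id column plus at least one data column")
    ids <- df[[1L]]
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicated feature identifier(s): ",
             paste(unique(dup), collapse = ", "))
    vals <- df[, -1L, drop = FALSE]
    num <- suppressWarnings(
        vapply(vals, as.numeric, numeric(nrow(vals))))
    if (nrow(vals) == 1L) num <- matrix(num, nrow = 1L)
    bad <- which(is.na(num) & !(toupper(as.matrix(vals)) %in% "NA"),
                 arr.ind = TRUE)
    if (nrow(vals) && any(is.na(num))) {
        badIdx <- which(is.na(num), arr.ind = TRUE)[1L, ]
        stop("non-numeric value at row '", ids[badIdx[1L]], "', column '",
             colnames(vals)[badIdx[2L]], "'")
    }
    m <- matrix(num, nrow = nrow(vals),
                dimnames = list(ids, colnames(vals)))
    asExpressionMatrix(m)
}

#' Write an expression matrix as delimited text
#'
#' @param x expression matrix.
#' @param path output file path.
#' @param sep delimiter; default tab.
#' @return the path, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, sep = "\t") {
    x <- asExpressionMatrix(x)
    df <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.metadataPath <- function(path) paste0(path, ".meta.json")

#' Write a consensus-type matrix with provenance sidecar
#'
#' The matrix is written as TSV with the feature identifiers as header row
#' and first column; provenance (algorithm, k, iterations, proportion,
#' seed, or sources and weights for merges) goes to a JSON sidecar at
#' `<path>.meta.json`.
#'
#' @param x a [ConsensusResult-class], [MergeResult-class] or plain
#'   consensus-type matrix.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeConsensusMatrix <- function(x, path) {
    m <- consensusMatrix(x)
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    meta <- if (is(x, "ConsensusResult")) {
        list(type = "consensus", algorithm = x@algorithm@algorithm,
             distance = x@algorithm@distance,
             linkage = x@algorithm@linkage, k = x@k,
             iterations = x@iterations, proportion = x@proportion,
             seed = x@seed)
    } else if (is(x, "MergeResult")) {
        list(type = "merge", k = x@k, sources = x@sources,
             weights = x@weights)
    } else {
        list(type = "matrix")
    }
    jsonlite::write_json(meta, .metadataPath(path), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read a consensus-type matrix written by [writeConsensusMatrix()]
#'
#' @param path file path.
#' @return the numeric matrix, with any sidecar metadata attached as
#'   attribute `"metadata"`.
#' @export
readConsensusMatrix <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    m <- consensusMatrix(m)
    mp <- .metadataPath(path)
    if (file.exists(mp))
        attr(m, "metadata") <- jsonlite::read_json(mp, simplifyVector = TRUE)
    m
}

#' Write a robustness report as tidy TSV
#'
#' One row per (cluster, feature) with columns `cluster`, `feature_id`,
#' `membership_robustness`, `cluster_robustness`, `singleton_flag`,
#' `source`.
#'
#' @param report a [RobustnessReport-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeRobustnessReport <- function(report, path) {
    utils::write.table(as.data.frame(report), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write delta-K profiles as a TSV table
#'
#' @param profiles a [DeltaKProfile-class] or list of them.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeDeltaKTable <- function(profiles, path) {
    if (is(profiles, "DeltaKProfile"))
        profiles <- list(profiles)
    rows <- lapply(profiles, function(p)
        data.frame(source = p@source, k = p@k, auc = p@auc,
                   delta_k = p@deltaK, definition = p@definition))
    utils::write.table(do.call(rbind, rows), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
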