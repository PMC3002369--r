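#' Coerce input to a validated expression matrix
#'
#' Accepts a numeric matrix, a data.frame of numeric columns, or a
#' [SummarizedExperiment::SummarizedExperiment-class] (first assay) and
#' returns a numeric features x conditions matrix with unique row and
#' column identifiers and finite values.
#'
#' @param x the input data.
#' @return a numeric matrix.
#' @export
asExpressionMatrix <- function(x) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, 1L)
    if (is.data.frame(x))
        x <- as.matrix(x)
    if (!is.matrix(x) || !is.numeric(x))
        stop("expression data must be a numeric matrix ",
             "(or data.frame/SummarizedExperiment holding one)")
    if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
        stop("expression matrix must have unique row identifiers")
    if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
        stop("expression matrix column identifiers must be unique")
    if (is.null(colnames(x)))
        colnames(x) <- paste0("c", seq_len(ncol(x)))
    x
}

#' Keep the most variable features
#'
#' Retains the `n` rows with the highest sample variance across columns --
#' the usual pre-clustering reduction for expression matrices ("the genes
#' with the highest expression variance"). The original relative row order
#' is preserved; ties at the n-th rank break by row order.
#'
#' @param data expression matrix (anything [asExpressionMatrix()] accepts).
#' @param n number of rows to keep; must not exceed the row count.
#' @return the filtered matrix.
#' @examples
#' x <- matrix(c(1, 1, 1, 1, 0, 2, 0, 2, 5, -5, 5, -5), 3, byrow = TRUE,
#'             dimnames = list(c("flat", "mid", "wild"), NULL))
#' rownames(varianceFilter(x, 2))
#' @export
varianceFilter <- function(data, n) {
    x <- asExpressionMatrix(data)
    n <- as.integer(n)
    if (length(n) != 1L || is.na(n) || n < 1L)
        stop("'n' must be a single positive integer")
    if (n > nrow(x))
        stop("'n' (", n, ") exceeds the number of features (", nrow(x), ")")
    v <- apply(x, 1L, stats::var)
    keep <- sort(order(v, decreasing = TRUE)[seq_len(n)])
    x[keep, , drop = FALSE]
}

#' Scale rows to unit size for shape-based clustering
#'
#' Rescales each row so that clustering reflects the shape of the profile
#' rather than its magnitude. The default scales each row to unit
#' Euclidean norm; `method = "standardise"` mean-centres each row and
#' scales it to unit standard deviation instead. Rows that cannot be
#' scaled (all-zero rows, or constant rows under standardisation) are left
#' unscaled at zero after centring and flagged with a warning.
#'
#' @param data expression matrix.
#' @param method `"norm"` (unit Euclidean norm, the default) or
#'   `"standardise"`.
#' @return the rescaled matrix.
#' @examples
#' unitise(matrix(c(1, 1, 0, 0), 1, dimnames = list("a", NULL)))
#' @export
unitise <- function(data, method = c("norm", "standardise")) {
    x <- asExpressionMatrix(data)
    method <- match.arg(method)
    if (method == "norm") {
        nrm <- sqrt(rowSums(x^2))
        bad <- nrm == 0
        nrm[bad] <- 1
        out <- x / nrm
    } else {
        mu <- rowMeans(x)
        sd <- apply(x, 1L, stats::sd)
        bad <- is.na(sd) | sd == 0
        sd[bad] <- 1
        out <- (x - mu) / sd
    }
    if (any(bad))
        warning("rows could not be unitised (zero size) and were left ",
                "unscaled: ", paste(rownames(x)[bad], collapse = ", "))
    out
}

#' Transpose an expression matrix
#'
#' Swaps features and conditions (with their identifiers), e.g. to cluster
#' patients rather than genes. Involutive: transposing twice returns the
#' original matrix.
#'
#' @param data expression matrix.
#' @return the transposed matrix.
#' @export
transposeMatrix <- function(data) {
    x <- asExpressionMatrix(data)
    t(x)
}

#' Convert a consensus matrix to a dissimilarity
#'
#' Consensus-type matrices can serve directly as distance matrices in new
#' clustering experiments: features that always co-cluster are at distance
#' 0, features that never co-cluster at distance 1. Returns `1 - M` as a
#' [stats::dist] object, accepted as a precomputed dissimilarity by the
#' hierarchical and pam backends of [runClustering()].
#'
#' @param M a [ConsensusResult-class], [MergeResult-class] or plain
#'   consensus-type matrix.
#' @return a `dist` object.
#' @examples
#' M <- matrix(c(1, .8, .8, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' consensusToDistance(M)
#' @export
consensusToDistance <- function(M) {
    m <- consensusMatrix(M)
    stats::as.dist(1 - m)
}
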