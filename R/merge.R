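#' Merge consensus matrices by weighted averaging
#'
#' Combines consensus matrices from different algorithms or conditions run
#' at the same cluster number into a single merge consensus matrix by
#' elementwise weighted averaging. Merging blends the classification
#' behaviour of methodologically different algorithms: a pair scored as
#' fully consistent by one algorithm but inconsistent by another ends up
#' intermediate, penalising structures that only one method supports.
#' Weights are normalised internally to sum one, so any nonnegative scale
#' may be supplied; omitted weights mean equal weighting. Merging across
#' different cluster numbers is refused.
#'
#' A pair's never-co-sampled flag is carried over only if every source
#' flagged it: the merge exists precisely to fill in weak evidence.
#'
#' @param sources list of two or more [ConsensusResult-class] (or
#'   [MergeResult-class]) objects sharing identical ordered feature
#'   identifiers and the same k.
#' @param weights optional numeric vector, one weight in [0, 1] per
#'   source, not all zero. Default: equal weights.
#' @return a [MergeResult-class].
#' @examples
#' sim <- simulateProfiles(nPerProfile = 8, spikeCounts = c(0, 0, 0, 0),
#'                         seed = 3)
#' cc1 <- consensusCluster(sim, algorithmSpec("pam"), k = 4,
#'                         iterations = 15, seed = 3)
#' cc2 <- consensusCluster(sim, algorithmSpec("hierarchical"), k = 4,
#'                         iterations = 15, seed = 3)
#' m <- mergeConsensus(list(cc1, cc2))
#' range(consensusMatrix(m))
#' @export
mergeConsensus <- function(sources, weights = NULL) {
    if (!is.list(sources) || length(sources) < 2L)
        stop("'sources' must be a list of at least two consensus results")
    mats <- lapply(sources, consensusMatrix)
    ids <- rownames(mats[[1L]])
    for (i in seq_along(mats)[-1L])
        if (!identical(rownames(mats[[i]]), ids))
            stop("source ", i, " has a different feature axis; all sources ",
                 "must share identical ordered feature identifiers")
    ks <- vapply(sources, function(s)
        if (is(s, "ConsensusResult") || is(s, "MergeResult"))
            s@k else NA_integer_, integer(1))
    if (any(!is.na(ks)) && length(unique(ks[!is.na(ks)])) > 1L)
        stop("sources were produced at different cluster numbers (",
             paste(unique(ks[!is.na(ks)]), collapse = ", "),
             "); only results with the same k can be merged")
    k <- if (any(!is.na(ks))) unique(ks[!is.na(ks)]) else NA_integer_

    if (is.null(weights))
        weights <- rep(1, length(sources))
    if (!is.numeric(weights) || length(weights) != length(sources))
        stop("'weights' must supply one value per source")
    if (any(weights < 0 | weights > 1))
        stop("'weights' must lie in [0, 1]")
    if (sum(weights) == 0)
        stop("'weights' must not all be zero")
    w <- weights / sum(weights)

    merged <- matrix(0, nrow(mats[[1L]]), ncol(mats[[1L]]),
                     dimnames = dimnames(mats[[1L]]))
    for (i in seq_along(mats))
        merged <- merged + w[i] * mats[[i]]
    diag(merged) <- 1

    flags <- lapply(sources, function(s)
        if (is(s, "ConsensusResult") || is(s, "MergeResult"))
            s@neverCoSampled
        else matrix(FALSE, nrow(merged), ncol(merged),
                    dimnames = dimnames(merged)))
    never <- Reduce(`&`, flags)

    descr <- vapply(seq_along(sources), function(i) {
        s <- sources[[i]]
        if (is(s, "ConsensusResult"))
            paste0(s@algorithm@algorithm, ".k", s@k, ".seed", s@seed)
        else if (is(s, "MergeResult"))
            paste0("merge.k", s@k)
        else paste0("matrix", i)
    }, character(1))

    new("MergeResult", consensus = merged, k = as.integer(k),
        weights = w, sources = descr, neverCoSampled = never)
}

#' @describeIn MergeResult the merged consensus matrix.
#' @param x a `MergeResult`.
#' @export
setMethod("consensusMatrix", "MergeResult", function(x) x@consensus)

setMethod("show", "MergeResult", function(object) {
    cat("MergeResult:", nrow(object@consensus), "features | k =",
        object@k, "\n")
    cat("  sources:", paste(object@sources, collapse = ", "), "\n")
    cat("  weights:", paste(round(object@weights, 3), collapse = ", "),
        "\n")
})
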