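#' Subsample rows of an expression matrix
#'
#' Draws `round(proportion * N)` distinct rows without replacement using
#' the current RNG state; the column set is unchanged. With
#' `proportion = 1` the full matrix is returned in its original row order.
#'
#' @param data expression matrix.
#' @param proportion fraction of rows in (0, 1].
#' @return a list with elements `matrix` (the row subset, rows in original
#'   relative order) and `ids` (the sampled identifiers).
#' @examples
#' x <- matrix(rnorm(40), 10, dimnames = list(paste0("g", 1:10), NULL))
#' set.seed(1)
#' subsampleRows(x, 0.8)$ids
#' @export
subsampleRows <- function(data, proportion) {
    x <- asExpressionMatrix(data)
    if (!is.numeric(proportion) || length(proportion) != 1L ||
        proportion <= 0 || proportion > 1)
        stop("'proportion' must be a single value in (0, 1]")
    n <- round(proportion * nrow(x))
    if (n < 1L)
        stop("'proportion' = ", proportion, " selects no rows")
    idx <- sort(sample.int(nrow(x), n))
    list(matrix = x[idx, , drop = FALSE], ids = rownames(x)[idx])
}

#' Connectivity matrix of a clustering over a feature universe
#'
#' The per-iteration binary matrix recording co-clustering: entry (i, j)
#' is 1 when both features were sampled and assigned to the same cluster,
#' 0 otherwise. The diagonal is 1 for sampled features and 0 for unsampled
#' ones, so that summed connectivity and indicator matrices stay aligned.
#'
#' @param assignment a [ClusterAssignment-class] on the sampled subset.
#' @param universe ordered character vector of all feature identifiers;
#'   must contain every assigned feature.
#' @return an N x N integer 0/1 matrix over `universe`.
#' @examples
#' spec <- algorithmSpec()
#' a <- new("ClusterAssignment", labels = c(a = 1L, b = 1L, c = 2L),
#'          k = 2L, algorithm = spec)
#' connectivityMatrix(a, c("a", "b", "c", "d"))
#' @export
connectivityMatrix <- function(assignment, universe) {
    stopifnot(is(assignment, "ClusterAssignment"), is.character(universe))
    lab <- assignment@labels
    if (!all(names(lab) %in% universe))
        stop("assignment references identifiers outside the universe: ",
             paste(setdiff(names(lab), universe), collapse = ", "))
    n <- length(universe)
    m <- matrix(0L, n, n, dimnames = list(universe, universe))
    idx <- match(names(lab), universe)
    m[idx, idx] <- (outer(lab, lab, "==")) * 1L
    m
}

#' Indicator matrix of a sampled subset
#'
#' The per-iteration binary matrix recording co-sampling: entry (i, j) is
#' 1 when both features were present in the subsample. An empty sample
#' yields an all-zero matrix (degenerate, but valid).
#'
#' @param sampledIds character vector of sampled feature identifiers.
#' @param universe ordered character vector of all feature identifiers.
#' @return an N x N integer 0/1 matrix over `universe`.
#' @examples
#' indicatorMatrix(c("a", "b"), c("a", "b", "c"))
#' @export
indicatorMatrix <- function(sampledIds, universe) {
    stopifnot(is.character(universe))
    sampledIds <- as.character(sampledIds)
    if (!all(sampledIds %in% universe))
        stop("sampled identifiers outside the universe: ",
             paste(setdiff(sampledIds, universe), collapse = ", "))
    n <- length(universe)
    m <- matrix(0L, n, n, dimnames = list(universe, universe))
    idx <- match(sampledIds, universe)
    m[idx, idx] <- 1L
    m
}

#' Consensus clustering by row resampling
#'
#' The consensus clustering engine. For each iteration a proportion of
#' rows is drawn without replacement, the subsample is clustered with the
#' requested backend, and binary connectivity (co-clustered) and indicator
#' (co-sampled) matrices are accumulated. The consensus matrix is their
#' elementwise quotient: the frequency with which two features co-cluster
#' among the iterations where both were sampled. Pairs never drawn
#' together get consensus 0 and are flagged in `neverCoSampled`. The
#' reference clustering is obtained by clustering the full data under the
#' identical algorithm and parameters.
#'
#' Per-iteration seeds are derived deterministically from the master seed,
#' so iterations could run in any order with identical results, and a rerun
#' with the same inputs reproduces the consensus matrix bitwise. An
#' iteration whose subsample defeats the backend is retried with a fresh
#' draw up to `maxRetries` times before the run aborts.
#'
#' @param data expression matrix (anything [asExpressionMatrix()] accepts).
#' @param spec an [AlgorithmSpec-class] naming a registered backend.
#' @param k requested cluster count (2 <= k <= subsample size).
#' @param iterations number of resampling iterations; default 100.
#' @param proportion row subsampling fraction; default 0.8.
#' @param seed master RNG seed.
#' @param keepAssignments retain per-iteration assignments (lists with
#'   `ids` and `labels`) for inspection or independent recounting; off by
#'   default to bound memory.
#' @param maxRetries bounded retry count for failing iterations.
#' @return a [ConsensusResult-class].
#' @examples
#' sim <- simulateProfiles(nPerProfile = 6, spikeCounts = c(0, 0, 0, 0),
#'                         sigma = 0.05, seed = 7)
#' cc <- consensusCluster(sim, algorithmSpec("pam"), k = 4,
#'                        iterations = 20, seed = 7)
#' range(consensusMatrix(cc))
#' @export
consensusCluster <- function(data, spec = algorithmSpec(), k,
                             iterations = 100L, proportion = 0.8,
                             seed = 1L, keepAssignments = FALSE,
                             maxRetries = 10L) {
    x <- asExpressionMatrix(data)
    if (!all(is.finite(x)))
        stop("data contains missing or non-finite values")
    N <- nrow(x)
    ids <- rownames(x)
    k <- as.integer(k)
    iterations <- as.integer(iterations)
    seed <- as.integer(seed)
    if (iterations < 1L)
        stop("'iterations' must be >= 1")
    if (proportion <= 0 || proportion > 1)
        stop("'proportion' must lie in (0, 1]")
    nSub <- round(proportion * N)
    if (nSub < k)
        stop("subsample of ", nSub, " rows cannot be clustered into k = ",
             k, " groups")
    .getAlgorithm(spec@algorithm)   # fail early on unknown backends

    set.seed(seed)
    iterSeeds <- sample.int(2147483646L, iterations)

    conn <- matrix(0L, N, N, dimnames = list(ids, ids))
    ind <- matrix(0L, N, N, dimnames = list(ids, ids))
    kept <- if (keepAssignments) vector("list", iterations) else list()

    for (b in seq_len(iterations)) {
        lab <- NULL
        for (try in 0:maxRetries) {
            trySeed <- (iterSeeds[b] - 1L + try) %% 2147483646L + 1L
            set.seed(trySeed)
            idx <- sort(sample.int(N, nSub))
            asg <- tryCatch(
                runClustering(x[idx, , drop = FALSE], k, spec,
                              seed = trySeed),
                error = function(e) e)
            if (!inherits(asg, "error")) {
                lab <- asg@labels
                break
            }
            if (try == maxRetries)
                stop("iteration ", b, " failed after ", maxRetries,
                     " retries: ", conditionMessage(asg))
        }
        co <- outer(lab, lab, "==")
        conn[idx, idx] <- conn[idx, idx] + co
        ind[idx, idx] <- ind[idx, idx] + 1L
        if (keepAssignments)
            kept[[b]] <- list(ids = ids[idx], labels = lab)
    }

    M <- matrix(0, N, N, dimnames = list(ids, ids))
    pos <- ind > 0
    M[pos] <- conn[pos] / ind[pos]
    diag(M) <- 1
    never <- !pos
    diag(never) <- FALSE
    if (any(never))
        message("consensus run (", spec@algorithm, ", k = ", k, "): ",
                sum(never) / 2, " feature pair(s) were never co-sampled; ",
                "their consensus is 0 by convention -- consider more ",
                "iterations")

    reference <- runClustering(x, k, spec, seed = seed)
    new("ConsensusResult",
        consensus = M, connectivitySum = conn, indicatorSum = ind,
        reference = reference, algorithm = spec, k = k,
        iterations = iterations, proportion = proportion, seed = seed,
        neverCoSampled = never, assignments = kept)
}

## ---- accessors -------------------------------------------------------------

#' @describeIn ConsensusResult the consensus matrix.
#' @param x a `ConsensusResult`.
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x) x@consensus)

#' @describeIn ConsensusResult the full-data reference clustering.
#' @export
setMethod("referenceClustering", "ConsensusResult", function(x) x@reference)

#' @export
setMethod("consensusMatrix", "matrix", function(x) {
    msg <- .validConsensusMatrix(x)
    if (length(msg))
        stop("not a consensus-type matrix: ", paste(msg, collapse = "; "))
    x
})

setMethod("show", "ConsensusResult", function(object) {
    cat("ConsensusResult:", nrow(object@consensus), "features | k =",
        object@k, "|", object@algorithm@algorithm, "\n")
    cat("  iterations:", object@iterations,
        "| proportion:", object@proportion,
        "| seed:", object@seed, "\n")
    off <- object@consensus[upper.tri(object@consensus)]
    cat("  off-diagonal consensus: mean", round(mean(off), 3),
        "| never co-sampled pairs:", sum(object@neverCoSampled) / 2, "\n")
})
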