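#' @import methods
NULL

.isSquareNumeric <- function(m) {
    is.matrix(m) && is.numeric(m) && nrow(m) == ncol(m)
}

.isSymmetricNamed <- function(m, tol = 1e-8) {
    .isSquareNumeric(m) &&
        !is.null(rownames(m)) &&
        identical(rownames(m), colnames(m)) &&
        max(abs(m - t(m))) <= tol
}

#' Clustering backend specification
#'
#' Describes a clustering backend and the parameters it is run with: the
#' registry name of the algorithm, the distance metric, the linkage (used by
#' hierarchical backends only) and an open list of backend-specific
#' parameters such as the k-means update variant or the number of restarts.
#'
#' @slot algorithm registry name of the backend (see [listAlgorithms()]).
#' @slot distance distance metric name; one of `"euclidean"`, `"manhattan"`,
#'   `"maximum"`, `"canberra"`, `"minkowski"`.
#' @slot linkage agglomeration method for hierarchical backends; one of
#'   `"average"`, `"complete"`, `"single"`, `"ward.D2"`.
#' @slot params named list of extra backend parameters.
#'
#' @seealso [algorithmSpec()] for the user-facing constructor.
#' @export
setClass("AlgorithmSpec",
    slots = c(
        algorithm = "character",
        distance = "character",
        linkage = "character",
        params = "list"
    ),
    prototype = list(
        algorithm = "hierarchical",
        distance = "euclidean",
        linkage = "average",
        params = list()
    )
)

.supportedDistances <- c("euclidean", "manhattan", "maximum", "canberra",
                         "minkowski")
.supportedLinkages <- c("average", "complete", "single", "ward.D2")

setValidity("AlgorithmSpec", function(object) {
    msg <- character(0)
    if (length(object@algorithm) != 1L || !nzchar(object@algorithm))
        msg <- c(msg, "'algorithm' must be a single non-empty string")
    if (length(object@distance) != 1L ||
        !object@distance %in% .supportedDistances)
        msg <- c(msg, paste0("'distance' must be one of: ",
                             paste(.supportedDistances, collapse = ", ")))
    if (length(object@linkage) != 1L ||
        !object@linkage %in% .supportedLinkages)
        msg <- c(msg, paste0("'linkage' must be one of: ",
                             paste(.supportedLinkages, collapse = ", ")))
    if (length(object@params) &&
        (is.null(names(object@params)) || any(!nzchar(names(object@params)))))
        msg <- c(msg, "'params' must be a fully named list")
    if (length(msg)) msg else TRUE
})

#' Discrete clustering result
#'
#' A hard assignment of features to clusters. Labels are canonicalised by
#' order of first appearance in row order, so identical partitions always
#' carry identical labels. A backend may return fewer than `k` non-empty
#' clusters; this is recorded, not repaired.
#'
#' @slot labels integer vector of cluster indices in `1..k`, named by
#'   feature identifier.
#' @slot k the requested number of clusters.
#' @slot algorithm the [AlgorithmSpec-class] that produced the assignment.
#'
#' @seealso [clusterLabels()], [clusterIndexSets()], [clusterSizes()]
#' @export
setClass("ClusterAssignment",
    slots = c(
        labels = "integer",
        k = "integer",
        algorithm = "AlgorithmSpec"
    )
)

setValidity("ClusterAssignment", function(object) {
    msg <- character(0)
    lab <- object@labels
    if (is.null(names(lab)) || any(!nzchar(names(lab))))
        msg <- c(msg, "every label must be named by a feature identifier")
    else if (anyDuplicated(names(lab)))
        msg <- c(msg, "feature identifiers must be unique")
    if (anyNA(lab))
        msg <- c(msg, "labels must not contain NA")
    else {
        if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
            msg <- c(msg, "'k' must be a single positive integer")
        else if (length(lab) && (min(lab) < 1L || max(lab) > object@k))
            msg <- c(msg, "labels must lie in 1..k")
    }
    if (length(msg)) msg else TRUE
})

#' Virtual parent for consensus-type matrices
#'
#' Both single-algorithm [ConsensusResult-class] objects and
#' [MergeResult-class] objects expose an N x N symmetric matrix with entries
#' in [0, 1] and unit diagonal through [consensusMatrix()]; downstream
#' operations (robustness, CDF/AUC, consensus-as-distance) dispatch on this
#' class.
#'
#' @export
setClass("ConsensusMatrixLike", representation("VIRTUAL"))

#' Consensus clustering result
#'
#' The output of [consensusCluster()]: the consensus matrix, the summed
#' connectivity and indicator matrices it was derived from, the full-data
#' reference clustering obtained under identical conditions, and the
#' resampling provenance.
#'
#' @slot consensus N x N symmetric matrix in [0, 1] with unit diagonal;
#'   entry (i, j) is the fraction of iterations in which features i and j
#'   co-clustered, among iterations where both were sampled.
#' @slot connectivitySum N x N matrix of co-clustering counts.
#' @slot indicatorSum N x N matrix of co-sampling counts.
#' @slot reference [ClusterAssignment-class] on the full data.
#' @slot algorithm the [AlgorithmSpec-class] used.
#' @slot k requested cluster count.
#' @slot iterations number of resampling iterations performed.
#' @slot proportion row subsampling fraction in (0, 1].
#' @slot seed master RNG seed of the run.
#' @slot neverCoSampled logical matrix flagging pairs that were never drawn
#'   together (their consensus entry is 0 by convention).
#' @slot assignments optionally retained per-iteration assignments, a list
#'   with elements `ids` (sampled identifiers) and `labels` per iteration.
#'
#' @export
setClass("ConsensusResult",
    contains = "ConsensusMatrixLike",
    slots = c(
        consensus = "matrix",
        connectivitySum = "matrix",
        indicatorSum = "matrix",
        reference = "ClusterAssignment",
        algorithm = "AlgorithmSpec",
        k = "integer",
        iterations = "integer",
        proportion = "numeric",
        seed = "integer",
        neverCoSampled = "matrix",
        assignments = "list"
    )
)

.validConsensusMatrix <- function(m) {
    msg <- character(0)
    if (!.isSymmetricNamed(m))
        msg <- c(msg, "consensus matrix must be square, symmetric and named")
    else {
        if (min(m) < -1e-12 || max(m) > 1 + 1e-12)
            msg <- c(msg, "consensus entries must lie in [0, 1]")
        if (max(abs(diag(m) - 1)) > 1e-12)
            msg <- c(msg, "consensus diagonal must be 1")
    }
    msg
}

setValidity("ConsensusResult", function(object) {
    msg <- .validConsensusMatrix(object@consensus)
    cs <- object@connectivitySum
    is <- object@indicatorSum
    if (!identical(dim(cs), dim(object@consensus)) ||
        !identical(dim(is), dim(object@consensus)))
        msg <- c(msg, "count matrices must match the consensus dimensions")
    else {
        if (any(cs > is + 1e-9))
            msg <- c(msg, "connectivity counts cannot exceed indicator counts")
        if (any(is > object@iterations + 1e-9))
            msg <- c(msg, "indicator counts cannot exceed the iteration count")
        pos <- is > 0
        if (any(pos)) {
            q <- cs[pos] / is[pos]
            if (max(abs(q - object@consensus[pos])) > 1e-8)
                msg <- c(msg,
                    "consensus must equal connectivity/indicator where defined")
        }
    }
    if (object@proportion <= 0 || object@proportion > 1)
        msg <- c(msg, "'proportion' must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Merged consensus matrix
#'
#' The weighted elementwise average of two or more consensus matrices
#' obtained at the same cluster number, produced by [mergeConsensus()].
#' Weights are stored after normalisation to sum one.
#'
#' @slot consensus the merged N x N consensus-type matrix.
#' @slot k the shared cluster count of the sources.
#' @slot weights normalised weight vector, one entry per source.
#' @slot sources character descriptors of the merged sources.
#' @slot neverCoSampled logical matrix; a pair is flagged only if every
#'   source flagged it.
#'
#' @export
setClass("MergeResult",
    contains = "ConsensusMatrixLike",
    slots = c(
        consensus = "matrix",
        k = "integer",
        weights = "numeric",
        sources = "character",
        neverCoSampled = "matrix"
    )
)

setValidity("MergeResult", function(object) {
    msg <- .validConsensusMatrix(object@consensus)
    if (length(object@weights) != length(object@sources))
        msg <- c(msg, "one weight per source is required")
    if (abs(sum(object@weights) - 1) > 1e-8)
        msg <- c(msg, "stored weights must be normalised to sum 1")
    if (length(msg)) msg else TRUE
})

#' Cluster and membership robustness report
#'
#' Per-cluster robustness (mean within-cluster consensus over unordered
#' member pairs) and per-member membership robustness (mean consensus
#' between a member and the rest of its cluster), scored against an
#' explicit reference clustering. Singleton clusters take the conventional
#' value 1 and are flagged.
#'
#' @slot clusterRobustness numeric vector named by cluster index.
#' @slot membership data.frame with columns `cluster`, `feature_id`,
#'   `membership_robustness`.
#' @slot reference the [ClusterAssignment-class] the report is cast onto.
#' @slot source descriptor of the scored matrix (algorithm name or "merge").
#' @slot singletons integer vector of singleton cluster indices.
#'
#' @export
setClass("RobustnessReport",
    slots = c(
        clusterRobustness = "numeric",
        membership = "data.frame",
        reference = "ClusterAssignment",
        source = "character",
        singletons = "integer"
    )
)

setValidity("RobustnessReport", function(object) {
    msg <- character(0)
    cr <- object@clusterRobustness
    mr <- object@membership$membership_robustness
    if (length(cr) && (min(cr) < -1e-12 || max(cr) > 1 + 1e-12))
        msg <- c(msg, "cluster robustness values must lie in [0, 1]")
    if (length(mr) && (min(mr) < -1e-12 || max(mr) > 1 + 1e-12))
        msg <- c(msg, "membership robustness values must lie in [0, 1]")
    need <- c("cluster", "feature_id", "membership_robustness")
    if (!all(need %in% names(object@membership)))
        msg <- c(msg, paste("membership table needs columns:",
                            paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Empirical CDF of consensus values
#'
#' The empirical cumulative distribution of the off-diagonal (i < j)
#' entries of a consensus-type matrix, evaluated at each distinct value.
#'
#' @slot values ascending distinct consensus entries.
#' @slot cdf CDF evaluated at each value; nondecreasing, ends at 1.
#' @slot nPairs the N(N-1)/2 pair count used as denominator.
#'
#' @export
setClass("ConsensusCDF",
    slots = c(values = "numeric", cdf = "numeric", nPairs = "integer")
)

setValidity("ConsensusCDF", function(object) {
    msg <- character(0)
    if (length(object@values) != length(object@cdf))
        msg <- c(msg, "'values' and 'cdf' must have equal length")
    if (length(object@values)) {
        if (is.unsorted(object@values, strictly = TRUE))
            msg <- c(msg, "'values' must be strictly ascending")
        if (min(object@values) < -1e-12 || max(object@values) > 1 + 1e-12)
            msg <- c(msg, "'values' must lie in [0, 1]")
        if (is.unsorted(object@cdf))
            msg <- c(msg, "'cdf' must be nondecreasing")
        if (abs(object@cdf[length(object@cdf)] - 1) > 1e-12)
            msg <- c(msg, "'cdf' must end at 1")
    }
    if (length(msg)) msg else TRUE
})

#' AUC and delta-K across a range of cluster numbers
#'
#' For each evaluated cluster number the area under the consensus CDF and
#' the change in that area relative to the previous cluster number, under
#' either the relative or the plain-difference definition.
#'
#' @slot k ascending integer vector of evaluated cluster numbers.
#' @slot auc AUC per cluster number.
#' @slot deltaK change in AUC per cluster number; the first entry is the
#'   seed value AUC(k\[1\]) under the relative definition and NA under the
#'   difference definition.
#' @slot definition `"relative"` or `"difference"`.
#' @slot source descriptor of the matrix family the profile was computed
#'   from (an algorithm name or `"merge"`).
#'
#' @export
setClass("DeltaKProfile",
    slots = c(
        k = "integer",
        auc = "numeric",
        deltaK = "numeric",
        definition = "character",
        source = "character"
    )
)

setValidity("DeltaKProfile", function(object) {
    msg <- character(0)
    if (length(object@k) != length(object@auc) ||
        length(object@k) != length(object@deltaK))
        msg <- c(msg, "'k', 'auc' and 'deltaK' must align")
    if (length(object@k) > 1 && is.unsorted(object@k, strictly = TRUE))
        msg <- c(msg, "'k' must be strictly ascending")
    ok <- !is.na(object@auc)
    if (any(object@auc[ok] < -1e-12 | object@auc[ok] > 1 + 1e-12))
        msg <- c(msg, "AUC values must lie in [0, 1]")
    if (!object@definition %in% c("relative", "difference"))
        msg <- c(msg, "'definition' must be \"relative\" or \"difference\"")
    if (length(msg)) msg else TRUE
})

#' Bundle of a full consensus clustering experiment
#'
#' Everything produced by [runConsensusExperiment()]: per-algorithm
#' consensus results for every cluster number, merged matrices per cluster
#' number, robustness reports, delta-K profiles, the configuration used and
#' a plain-text log.
#'
#' @slot consensus named list of [ConsensusResult-class], one per
#'   (algorithm, k) cell, named `"<algorithm>.k<k>"`.
#' @slot merges named list of [MergeResult-class], named `"k<k>"`.
#' @slot robustness named list of [RobustnessReport-class].
#' @slot deltaK named list of [DeltaKProfile-class], one per algorithm plus
#'   `"merge"` when merges exist.
#' @slot config the evaluated configuration, as a named list.
#' @slot log character vector of log lines (seeds, timings, degenerate-case
#'   flags, per-cell failures).
#'
#' @export
setClass("ConsensusExperiment",
    slots = c(
        consensus = "list",
        merges = "list",
        robustness = "list",
        deltaK = "list",
        config = "list",
        log = "character"
    )
)
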