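#' Extract the consensus matrix
#'
#' Returns the N x N symmetric consensus-type matrix ([0, 1] entries, unit
#' diagonal) from a consensus or merge result, or validates and returns a
#' plain matrix supplied directly.
#'
#' @param x a [ConsensusResult-class], [MergeResult-class] or a plain named
#'   symmetric numeric matrix.
#' @return a numeric matrix with identical row and column names.
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))

#' Reference clustering of a consensus result
#'
#' The clustering of the full data obtained under the same algorithm and
#' parameters as the resampled runs; it supplies the cluster index sets
#' against which robustness is scored.
#'
#' @param x a [ConsensusResult-class].
#' @return a [ClusterAssignment-class].
#' @export
setGeneric("referenceClustering",
    function(x) standardGeneric("referenceClustering"))

#' Cluster labels of an assignment
#'
#' @param x a [ClusterAssignment-class].
#' @return an integer vector of cluster indices named by feature identifier.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Members of each cluster
#'
#' @param x a [ClusterAssignment-class].
#' @return a list mapping cluster index to the character vector of member
#'   feature identifiers; empty clusters are omitted.
#' @export
setGeneric("clusterIndexSets",
    function(x) standardGeneric("clusterIndexSets"))

#' Cluster sizes
#'
#' @param x a [ClusterAssignment-class].
#' @return an integer vector of member counts named by cluster index.
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' Area under the consensus CDF
#'
#' Integrates the empirical CDF of consensus values stepwise over its
#' distinct values: AUC = sum over i >= 2 of (x_i - x_(i-1)) CDF(x_i).
#' A perfectly consistent consensus matrix (off-diagonal entries only 0 and
#' 1, both present) yields exactly 1.
#'
#' @param x a [ConsensusCDF-class], or any object accepted by
#'   [consensusCDF()] (the CDF is computed first).
#' @return a single numeric value in [0, 1]. A single-valued CDF yields 0
#'   by the empty-sum convention, with a warning flagging the degeneracy.
#' @export
setGeneric("consensusAUC", function(x) standardGeneric("consensusAUC"))

#' Estimate the cluster number from a delta-K profile
#'
#' The optimal cluster number is read from peaks of the delta-K curve. A
#' peak is a local maximum: an evaluated k whose delta-K value is strictly
#' greater than both neighbouring values on the curve (the seed entry at
#' the smallest k serves as left boundary and is itself never a candidate;
#' the largest evaluated k is never a peak, since a curve still rising at
#' the right edge of the range shows no peak). Among peaks the one with
#' the largest delta-K wins; ties break toward smaller k. A profile with no
#' peak falls back to the global argmax over the candidates, flagged
#' `"no-peak"`; an entirely flat profile falls back to the smallest
#' evaluated k, flagged `"flat"`.
#'
#' @param profile a [DeltaKProfile-class].
#' @return the estimated cluster number as an integer scalar, with
#'   attribute `flag` set to `"peak"`, `"no-peak"` or `"flat"`. If every
#'   candidate is NA, `NA_integer_` is returned with flag `"undefined"`.
#' @export
setGeneric("estimateK", function(profile) standardGeneric("estimateK"))
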