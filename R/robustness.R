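## Robustness of a reference clustering structure under a consensus-type
## matrix. The matrix may come from a single-algorithm consensus run or
## from a merge; the same reference can be cast onto either, which is what
## makes consensus and merged results directly comparable.

.alignConsensus <- function(M, reference) {
    m <- consensusMatrix(M)
    ids <- names(reference@labels)
    if (!all(ids %in% rownames(m)))
        stop("consensus matrix lacks features of the reference clustering: ",
             paste(utils::head(setdiff(ids, rownames(m))), collapse = ", "))
    m[ids, ids, drop = FALSE]
}

#' Cluster robustness
#'
#' For each cluster of the reference structure, the mean consensus over
#' all unordered pairs of its members: the within-cluster entries of the
#' consensus matrix with i < j are summed and divided by
#' N_k (N_k - 1) / 2, the number of such pairs (the diagonal is excluded).
#' A value of 1 means the members always co-clustered whenever co-sampled.
#' Singleton clusters take the conventional value 1 and are flagged with a
#' warning; use [robustnessReport()] to get the flags programmatically.
#'
#' @param M a [ConsensusResult-class], [MergeResult-class] or plain
#'   consensus-type matrix covering the reference's features.
#' @param reference the [ClusterAssignment-class] whose structure is
#'   scored.
#' @return a numeric vector of values in [0, 1], named by cluster index.
#' @examples
#' M <- matrix(c(1, 1, .5, 1, 1, .5, .5, .5, 1), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' ref <- new("ClusterAssignment", labels = c(a = 1L, b = 1L, c = 1L),
#'            k = 1L, algorithm = algorithmSpec())
#' clusterRobustness(M, ref)   # (1 + 0.5 + 0.5) / 3
#' @export
clusterRobustness <- function(M, reference) {
    m <- .alignConsensus(M, reference)
    sets <- clusterIndexSets(reference)
    singles <- names(sets)[lengths(sets) == 1L]
    if (length(singles))
        warning("singleton cluster(s) ", paste(singles, collapse = ", "),
                " assigned robustness 1 by convention")
    out <- vapply(sets, function(members) {
        n <- length(members)
        if (n < 2L) return(1)
        sub <- m[members, members]
        sum(sub[upper.tri(sub)]) / (n * (n - 1) / 2)
    }, numeric(1))
    out
}

#' Membership robustness
#'
#' For each member e_i of a reference cluster, the mean consensus between
#' e_i and every other member of that cluster: the row of the consensus
#' matrix restricted to the cluster, summed without the diagonal and
#' divided by N_k - 1. Low values mark members whose co-clustering with
#' the rest of the cluster was unreliable under resampling. Members of
#' singleton clusters take the conventional value 1 (flagged with a
#' warning).
#'
#' @inheritParams clusterRobustness
#' @return a data.frame with columns `cluster`, `feature_id` and
#'   `membership_robustness`, ordered by cluster then feature.
#' @examples
#' M <- matrix(c(1, 1, .5, 1, 1, .5, .5, .5, 1), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' ref <- new("ClusterAssignment", labels = c(a = 1L, b = 1L, c = 1L),
#'            k = 1L, algorithm = algorithmSpec())
#' membershipRobustness(M, ref)$membership_robustness  # 0.75 0.75 0.50
#' @export
membershipRobustness <- function(M, reference) {
    m <- .alignConsensus(M, reference)
    sets <- clusterIndexSets(reference)
    singles <- names(sets)[lengths(sets) == 1L]
    if (length(singles))
        warning("singleton cluster(s) ", paste(singles, collapse = ", "),
                " assigned membership robustness 1 by convention")
    rows <- lapply(names(sets), function(cl) {
        members <- sets[[cl]]
        n <- length(members)
        mi <- if (n < 2L) 1 else {
            sub <- m[members, members, drop = FALSE]
            (rowSums(sub) - diag(sub)) / (n - 1)
        }
        data.frame(cluster = as.integer(cl), feature_id = members,
                   membership_robustness = unname(mi),
                   row.names = NULL)
    })
    do.call(rbind, rows)
}

#' Full robustness report
#'
#' Computes cluster and membership robustness of a reference structure
#' under a consensus-type matrix and bundles them with the singleton flags
#' and a source descriptor into a [RobustnessReport-class]. For every
#' non-singleton cluster the cluster robustness equals the mean of its
#' members' membership robustness.
#'
#' @inheritParams clusterRobustness
#' @param source descriptor of the scored matrix, e.g. the algorithm name
#'   or `"merge"`; stored in the report and its serialisations.
#' @return a [RobustnessReport-class].
#' @export
robustnessReport <- function(M, reference, source = "consensus") {
    sets <- clusterIndexSets(reference)
    singles <- as.integer(names(sets)[lengths(sets) == 1L])
    cr <- withCallingHandlers(clusterRobustness(M, reference),
                              warning = function(w) {
                                  if (grepl("singleton", conditionMessage(w)))
                                      invokeRestart("muffleWarning")
                              })
    mr <- withCallingHandlers(membershipRobustness(M, reference),
                              warning = function(w) {
                                  if (grepl("singleton", conditionMessage(w)))
                                      invokeRestart("muffleWarning")
                              })
    new("RobustnessReport", clusterRobustness = cr, membership = mr,
        reference = reference, source = source, singletons = singles)
}

#' Tidy view of a robustness report
#'
#' @param x a [RobustnessReport-class].
#' @param ... ignored.
#' @return a data.frame with one row per (cluster, feature): columns
#'   `cluster`, `feature_id`, `membership_robustness`,
#'   `cluster_robustness`, `singleton_flag` and `source`.
#' @export
as.data.frame.RobustnessReport <- function(x, ...) {
    df <- x@membership
    df$cluster_robustness <-
        unname(x@clusterRobustness[as.character(df$cluster)])
    df$singleton_flag <- df$cluster %in% x@singletons
    df$source <- x@source
    df
}

setMethod("show", "RobustnessReport", function(object) {
    cat("RobustnessReport (source:", object@source, ")\n")
    cat("  cluster robustness:",
        paste(sprintf("%s=%.3f", names(object@clusterRobustness),
                      object@clusterRobustness), collapse = ", "), "\n")
    if (length(object@singletons))
        cat("  singleton clusters:",
            paste(object@singletons, collapse = ", "), "\n")
})
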