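# Independent brute-force oracles, deliberately written as naive loops so
# they share no code with the package implementation.

# Pair-counting recount of a consensus matrix from logged per-iteration
# assignments (lists with $ids and $labels).
naiveConsensus <- function(assignments, universe) {
    n <- length(universe)
    conn <- matrix(0, n, n, dimnames = list(universe, universe))
    ind <- matrix(0, n, n, dimnames = list(universe, universe))
    for (asg in assignments) {
        for (a in asg$ids) {
            for (b in asg$ids) {
                ind[a, b] <- ind[a, b] + 1
                if (asg$labels[a] == asg$labels[b])
                    conn[a, b] <- conn[a, b] + 1
            }
        }
    }
    M <- matrix(0, n, n, dimnames = list(universe, universe))
    for (i in seq_len(n)) for (j in seq_len(n))
        if (ind[i, j] > 0) M[i, j] <- conn[i, j] / ind[i, j]
    diag(M) <- 1
    list(M = M, conn = conn, ind = ind)
}

# Nested-loop cluster robustness: mean over within-cluster pairs i < j.
naiveClusterRobustness <- function(M, labels) {
    ids <- names(labels)
    out <- c()
    for (cl in sort(unique(labels))) {
        members <- ids[labels == cl]
        n <- length(members)
        if (n < 2) { out[as.character(cl)] <- 1; next }
        s <- 0
        for (i in seq_len(n - 1)) for (j in (i + 1):n)
            s <- s + M[members[i], members[j]]
        out[as.character(cl)] <- s / (n * (n - 1) / 2)
    }
    out
}

# Nested-loop membership robustness: mean consensus of a member to the
# rest of its cluster.
naiveMembershipRobustness <- function(M, labels) {
    ids <- names(labels)
    out <- numeric(0)
    for (cl in sort(unique(labels))) {
        members <- ids[labels == cl]
        for (e in members) {
            if (length(members) < 2) { out[e] <- 1; next }
            s <- 0
            for (j in members) if (j != e) s <- s + M[e, j]
            out[e] <- s / (length(members) - 1)
        }
    }
    out
}

# Counting-loop CDF over off-diagonal i < j entries.
naiveCDF <- function(M, at) {
    n <- nrow(M)
    total <- n * (n - 1) / 2
    vapply(at, function(c) {
        cnt <- 0
        for (i in seq_len(n - 1)) for (j in (i + 1):n)
            if (M[i, j] <= c) cnt <- cnt + 1
        cnt / total
    }, numeric(1))
}

# Stepwise summation of the CDF over its distinct sorted values.
naiveAUC <- function(M) {
    n <- nrow(M)
    vals <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
        vals <- c(vals, M[i, j])
    xs <- sort(unique(vals))
    if (length(xs) < 2) return(0)
    cdf <- naiveCDF(M, xs)
    a <- 0
    for (i in 2:length(xs)) a <- a + (xs[i] - xs[i - 1]) * cdf[i]
    a
}

# Random symmetric consensus-type matrix with unit diagonal.
randomConsensusMatrix <- function(n, ids = sprintf("f%02d", seq_len(n))) {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    diag(m) <- 1
    m
}

# Random partition guaranteed to have at least one member per cluster.
randomAssignment <- function(n, k, ids = sprintf("f%02d", seq_len(n))) {
    raw <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
    raw <- raw[sample.int(n)]
    labels <- as.integer(match(raw, unique(raw)))
    names(labels) <- ids
    new("ClusterAssignment", labels = labels,
        k = as.integer(k), algorithm = algorithmSpec())
}

# Two well-separated Gaussian point clouds.
twoClouds <- function(nPer = 10, d = 4, sep = 8, seed = 1) {
    set.seed(seed)
    x <- rbind(matrix(rnorm(nPer * d, 0), nPer),
               matrix(rnorm(nPer * d, sep), nPer))
    rownames(x) <- sprintf("p%02d", seq_len(2 * nPer))
    x
}
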