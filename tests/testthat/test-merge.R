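# Wraps a plain matrix as a minimal ConsensusResult so merges can be
# exercised with exactly controlled entries.
.asResult <- function(M, k = 2L, alg = "hierarchical", seed = 1L) {
    n <- nrow(M)
    raw <- rep(seq_len(k), length.out = n)
    labels <- as.integer(match(raw, unique(raw)))
    names(labels) <- rownames(M)
    ind <- matrix(100, n, n, dimnames = dimnames(M))
    conn <- M * 100
    new("ConsensusResult", consensus = M,
        connectivitySum = conn, indicatorSum = ind,
        reference = new("ClusterAssignment", labels = labels, k = k,
                        algorithm = algorithmSpec(alg)),
        algorithm = algorithmSpec(alg), k = k, iterations = 100L,
        proportion = 1, seed = seed,
        neverCoSampled = matrix(FALSE, n, n, dimnames = dimnames(M)),
        assignments = list())
}

.binaryMatrix <- function(n, ids = sprintf("f%02d", seq_len(n))) {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    half <- seq_len(n %/% 2)
    m[half, half] <- 1
    m[-half, -half] <- 1
    m
}

test_that("equal-weight merging is the elementwise arithmetic mean", {
    ids <- c("a", "b")
    M1 <- matrix(c(1, 0.2, 0.2, 1), 2, dimnames = list(ids, ids))
    M2 <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(ids, ids))
    m <- mergeConsensus(list(.asResult(M1), .asResult(M2)))
    expect_equal(consensusMatrix(m)["a", "b"], 0.5)
    expect_equal(m@weights, c(0.5, 0.5))
})

test_that("degenerate weights reproduce a single source and scaling the weights changes nothing", {
    set.seed(3)
    M1 <- randomConsensusMatrix(5)
    M2 <- randomConsensusMatrix(5)
    src <- list(.asResult(M1), .asResult(M2))
    expect_equal(consensusMatrix(mergeConsensus(src, c(1, 0))), M1)
    # weight normalisation identity: (2, 2) behaves exactly like (0.5, 0.5)
    expect_equal(
        consensusMatrix(suppressWarnings(mergeConsensus(src, c(1, 1)))),
        consensusMatrix(mergeConsensus(src, c(0.5, 0.5))))
})

test_that("three-way weighted merging matches an independent scalar loop", {
    set.seed(11)
    mats <- replicate(3, randomConsensusMatrix(6), simplify = FALSE)
    w <- c(0.5, 0.3, 0.2)
    m <- mergeConsensus(lapply(mats, .asResult), w)
    got <- consensusMatrix(m)
    for (i in 1:6) for (j in 1:6) {
        expected <- 0
        for (s in 1:3) expected <- expected + w[s] * mats[[s]][i, j]
        if (i == j) expected <- 1
        expect_equal(got[i, j], expected, tolerance = 1e-12)
    }
})

test_that("merged entries are convex combinations and merging a matrix with itself is the identity", {
    set.seed(21)
    M1 <- randomConsensusMatrix(7)
    M2 <- randomConsensusMatrix(7)
    merged <- consensusMatrix(mergeConsensus(list(.asResult(M1),
                                                  .asResult(M2)),
                                             c(0.7, 0.3)))
    expect_true(all(merged >= pmin(M1, M2) - 1e-12))
    expect_true(all(merged <= pmax(M1, M2) + 1e-12))
    expect_identical(merged, t(merged))
    expect_equal(diag(merged), setNames(rep(1, 7), rownames(M1)))

    self <- mergeConsensus(list(.asResult(M1), .asResult(M1)), c(0.9, 0.1))
    expect_equal(consensusMatrix(self), M1, tolerance = 1e-15)
})

test_that("merging validates k, feature axes and weights", {
    set.seed(2)
    M1 <- randomConsensusMatrix(4)
    M2 <- randomConsensusMatrix(4)
    expect_error(mergeConsensus(list(.asResult(M1))), "at least two")
    expect_error(mergeConsensus(list(.asResult(M1, k = 2L),
                                     .asResult(M2, k = 3L))),
                 "different cluster numbers")
    M3 <- randomConsensusMatrix(4, ids = letters[1:4])
    expect_error(mergeConsensus(list(.asResult(M1), .asResult(M3))),
                 "feature axis")
    src <- list(.asResult(M1), .asResult(M2))
    expect_error(mergeConsensus(src, c(0, 0)), "not all be zero")
    expect_error(mergeConsensus(src, c(0.5, 1.5)), "0, 1")
    expect_error(mergeConsensus(src, 1), "one value per source")
})

test_that("a merge is accepted by every downstream consumer", {
    ids <- sprintf("f%02d", 1:6)
    m <- mergeConsensus(list(.asResult(.binaryMatrix(6)),
                             .asResult(.binaryMatrix(6))))
    ref <- .asResult(.binaryMatrix(6))@reference
    expect_s4_class(robustnessReport(m, ref), "RobustnessReport")
    expect_equal(consensusAUC(m), 1)
    d <- consensusToDistance(m)
    expect_s3_class(d, "dist")
    # re-clustering a perfectly consistent merge at the same k recovers
    # its block structure
    lab <- clusterLabels(runClustering(d, 2, algorithmSpec("pam")))
    expect_true(all(table(lab, rep(1:2, each = 3)) %in% c(0, 3)))
})

test_that("never-co-sampled flags merge by conjunction", {
    set.seed(8)
    r1 <- .asResult(randomConsensusMatrix(4))
    r2 <- .asResult(randomConsensusMatrix(4))
    r1@neverCoSampled[1, 2] <- r1@neverCoSampled[2, 1] <- TRUE
    r1@neverCoSampled[1, 3] <- r1@neverCoSampled[3, 1] <- TRUE
    r2@neverCoSampled[1, 2] <- r2@neverCoSampled[2, 1] <- TRUE
    m <- mergeConsensus(list(r1, r2))
    expect_true(m@neverCoSampled[1, 2])
    expect_false(m@neverCoSampled[1, 3])  # only one source flagged it
})
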