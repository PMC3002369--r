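test_that("subsampling draws the right number of distinct rows and is seed-reproducible", {
    x <- matrix(rnorm(400), 100,
                dimnames = list(sprintf("g%03d", 1:100), paste0("c", 1:4)))

    set.seed(1)
    s <- subsampleRows(x, 0.8)
    expect_length(s$ids, 80)
    expect_false(anyDuplicated(s$ids) > 0)
    expect_identical(colnames(s$matrix), colnames(x))

    # proportion 1 returns the full matrix in original order
    set.seed(1)
    expect_identical(subsampleRows(x, 1)$matrix, x)

    # same seed, same draw
    set.seed(42); a <- subsampleRows(x, 0.5)$ids
    set.seed(42); b <- subsampleRows(x, 0.5)$ids
    expect_identical(a, b)

    expect_error(subsampleRows(x, 0), "proportion")
    expect_error(subsampleRows(x, 1.2), "proportion")
})

test_that("connectivity and indicator matrices follow their definitions, including unsampled features", {
    spec <- algorithmSpec()
    uni <- c("a", "b", "c")
    asg <- new("ClusterAssignment", labels = c(a = 1L, b = 1L, c = 2L),
               k = 2L, algorithm = spec)
    cm <- connectivityMatrix(asg, uni)
    expect_equal(cm["a", "b"], 1L)
    expect_equal(cm["a", "c"], 0L)
    expect_equal(cm["b", "c"], 0L)
    expect_identical(cm, t(cm))

    # all features in one cluster -> all ones
    one <- new("ClusterAssignment", labels = c(a = 1L, b = 1L, c = 1L),
               k = 1L, algorithm = spec)
    expect_true(all(connectivityMatrix(one, uni) == 1L))

    # unsampled feature d: zero row/column in both matrices
    uni4 <- c("a", "b", "c", "d")
    part <- new("ClusterAssignment", labels = c(a = 1L, b = 2L, c = 2L),
                k = 2L, algorithm = spec)
    cm4 <- connectivityMatrix(part, uni4)
    expect_true(all(cm4["d", ] == 0L) && all(cm4[, "d"] == 0L))
    expect_equal(cm4["b", "c"], 1L)

    im <- indicatorMatrix(c("a", "b"), uni)
    expect_equal(im["a", "b"], 1L)
    expect_equal(im["a", "c"], 0L)
    expect_true(all(indicatorMatrix(uni, uni) == 1L))
    expect_true(all(indicatorMatrix(character(0), uni) == 0L))

    expect_error(connectivityMatrix(part, c("a", "b")), "outside")
    expect_error(indicatorMatrix("z", uni), "outside")
})

test_that("with full sampling and a deterministic backend the consensus matrix is binary", {
    x <- twoClouds(nPer = 6)
    cc <- consensusCluster(x, algorithmSpec("hierarchical"), k = 2,
                           iterations = 7, proportion = 1, seed = 5)
    M <- consensusMatrix(cc)
    expect_true(all(M %in% c(0, 1)))
    # and equals the single-run connectivity matrix
    single <- connectivityMatrix(referenceClustering(cc), rownames(x))
    expect_equal(M, single + 0)
})

test_that("the engine's consensus matrix equals a brute-force pair recount of the logged assignments", {
    sim <- simulateProfiles(nPerProfile = 3, sigma = 0.3, seed = 2)
    x <- asExpressionMatrix(sim)[1:12, ]
    cc <- consensusCluster(x, algorithmSpec("pam"), k = 3,
                           iterations = 50, proportion = 0.75, seed = 17,
                           keepAssignments = TRUE)
    oracle <- naiveConsensus(cc@assignments, rownames(x))
    expect_equal(unname(cc@connectivitySum + 0), unname(oracle$conn))
    expect_equal(unname(cc@indicatorSum + 0), unname(oracle$ind))
    expect_equal(consensusMatrix(cc), oracle$M, tolerance = 0)

    # conservation: connectivity <= indicator <= iterations, everywhere
    expect_true(all(cc@connectivitySum <= cc@indicatorSum))
    expect_true(all(cc@indicatorSum <= 50))
})

test_that("consensus runs are reproducible and respect their preconditions", {
    x <- twoClouds(nPer = 8)
    c1 <- consensusCluster(x, algorithmSpec("kmeans"), k = 2,
                           iterations = 10, seed = 9)
    c2 <- consensusCluster(x, algorithmSpec("kmeans"), k = 2,
                           iterations = 10, seed = 9)
    expect_identical(consensusMatrix(c1), consensusMatrix(c2))

    expect_error(consensusCluster(x, algorithmSpec(), k = 14,
                                  iterations = 5, proportion = 0.8),
                 "cannot be clustered")
    expect_error(consensusCluster(x, algorithmSpec(), k = 2,
                                  iterations = 0), "iterations")
})

test_that("an iteration whose backend keeps failing aborts with a diagnostic after bounded retries", {
    nm <- paste0("failing_", as.integer(runif(1, 1, 1e6)))
    registerAlgorithm(nm, function(x, k, spec) stop("backend exploded"))
    x <- twoClouds(nPer = 4)
    expect_error(
        consensusCluster(x, algorithmSpec(nm), k = 2, iterations = 3,
                         maxRetries = 2),
        "failed after 2 retries")
})
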