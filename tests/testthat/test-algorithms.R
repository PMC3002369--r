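test_that("the registry round-trips, rejects duplicates and enforces the runner contract at first use", {
    nm <- paste0("testalg_", as.integer(runif(1, 1, 1e6)))
    registerAlgorithm(nm, function(x, k, spec) {
        rep_len(seq_len(k), nrow(as.matrix(x)))
    })
    expect_true(nm %in% listAlgorithms())
    expect_error(registerAlgorithm(nm, function(x, k, spec) 1),
                 "already registered")

    # a runner that labels only half the rows is caught when first run
    bad <- paste0(nm, "_bad")
    registerAlgorithm(bad, function(x, k, spec) {
        lab <- rep_len(seq_len(k), nrow(x) %/% 2)
        names(lab) <- rownames(x)[seq_along(lab)]
        lab
    })
    x <- twoClouds()
    expect_error(runClustering(x, 2, algorithmSpec(bad)),
                 "runner contract")
})

test_that("all built-in backends separate two well-separated point clouds", {
    x <- twoClouds(nPer = 10)
    truth <- rep(1:2, each = 10)
    for (alg in c("hierarchical", "kmeans", "pam")) {
        asg <- runClustering(x, 2, algorithmSpec(alg), seed = 3)
        lab <- clusterLabels(asg)
        expect_equal(length(lab), 20)
        expect_setequal(names(lab), rownames(x))
        # agreement up to label permutation
        expect_true(all(table(lab, truth) %in% c(0, 10)),
                    info = alg)
    }
})

test_that("k equal to the number of rows yields singleton clusters", {
    x <- twoClouds(nPer = 3)
    asg <- runClustering(x, nrow(x), algorithmSpec("hierarchical"))
    expect_equal(unname(clusterSizes(asg)), rep(1L, nrow(x)))
    # PAM is defined only for k < n; the backend surfaces that bound
    expect_error(runClustering(x, nrow(x), algorithmSpec("pam")))
})

test_that("pam on noiseless replicated base profiles matches brute-force nearest-medoid assignment", {
    sim <- simulateProfiles(nPerProfile = 30, sigma = 0, seed = 1,
                            spikeCounts = c(0, 0, 0, 0))
    x <- asExpressionMatrix(sim)
    truth <- SummarizedExperiment::rowData(sim)$profile
    asg <- runClustering(x, 4, algorithmSpec("pam"), seed = 1)
    lab <- clusterLabels(asg)

    # brute force: with sigma = 0 the optimal medoids are the four distinct
    # profiles; assign every row to its nearest
    centres <- simulationProfiles()$base
    nearest <- apply(x, 1, function(r)
        which.min(colSums((t(centres) - r)^2)))
    expect_true(all(table(lab, nearest) %in% c(0, 30)))
    expect_equal(unname(clusterSizes(asg)), rep(30L, 4))
    # and agreement with the generating truth
    expect_true(all(table(lab, truth) %in% c(0, 30)))
})

test_that("built-in backends are deterministic given data, spec and seed", {
    set.seed(99)
    x <- matrix(rnorm(200), 50)
    rownames(x) <- sprintf("r%02d", 1:50)
    for (alg in c("hierarchical", "kmeans", "pam")) {
        a1 <- runClustering(x, 3, algorithmSpec(alg), seed = 11)
        a2 <- runClustering(x, 3, algorithmSpec(alg), seed = 11)
        expect_identical(clusterLabels(a1), clusterLabels(a2), info = alg)
    }
})

test_that("labels are canonicalised by first appearance, making downstream matrices permutation-invariant", {
    ids <- letters[1:6]
    spec <- algorithmSpec()
    lab1 <- c(a = 1L, b = 1L, c = 2L, d = 2L, e = 3L, f = 3L)
    lab2 <- c(a = 3L, b = 3L, c = 1L, d = 1L, e = 2L, f = 2L)  # permuted
    a1 <- new("ClusterAssignment", labels = lab1, k = 3L, algorithm = spec)
    a2 <- new("ClusterAssignment", labels = lab2, k = 3L, algorithm = spec)
    expect_identical(connectivityMatrix(a1, ids),
                     connectivityMatrix(a2, ids))
})

test_that("invalid inputs are rejected with informative errors", {
    x <- twoClouds(nPer = 3)
    expect_error(runClustering(x, nrow(x) + 1, algorithmSpec()),
                 "exceeds")
    expect_error(runClustering(x, 1, algorithmSpec()), ">= 2")
    expect_error(runClustering(x, 2, algorithmSpec("nosuchalg")),
                 "unknown clustering algorithm")
    x[1, 1] <- NA
    expect_error(runClustering(x, 2, algorithmSpec()), "non-finite")
})

test_that("hierarchical and pam accept a precomputed dissimilarity, kmeans refuses one", {
    x <- twoClouds(nPer = 5)
    d <- dist(x)
    truth <- rep(1:2, each = 5)
    for (alg in c("hierarchical", "pam")) {
        lab <- clusterLabels(runClustering(d, 2, algorithmSpec(alg)))
        expect_true(all(table(lab, truth) %in% c(0, 5)), info = alg)
    }
    expect_error(runClustering(d, 2, algorithmSpec("kmeans")),
                 "coordinate data")
})
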