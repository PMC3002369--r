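.consensusOf <- function(entries, n, ids = sprintf("f%02d", seq_len(n))) {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[upper.tri(m)] <- entries
    m <- m + t(m)
    diag(m) <- 1
    m
}

test_that("the consensus CDF counts off-diagonal pairs at each distinct value", {
    # single-atom distribution
    M <- .consensusOf(rep(0.5, 3), 3)
    cc <- consensusCDF(M)
    expect_equal(cc@values, 0.5)
    expect_equal(cc@cdf, 1)
    expect_equal(cc@nPairs, 3L)

    # two-point distribution, half 0 and half 1
    M <- .consensusOf(c(0, 0, 0, 1, 1, 1), 4)
    cc <- consensusCDF(M)
    expect_equal(cc@values, c(0, 1))
    expect_equal(cc@cdf, c(0.5, 1))

    # random entries agree with a naive counting loop
    set.seed(4)
    M <- randomConsensusMatrix(7)   # 21 off-diagonal entries
    cc <- consensusCDF(M)
    expect_equal(cc@cdf, naiveCDF(M, cc@values), tolerance = 1e-15)

    expect_error(consensusCDF(matrix(1, 1, 1, dimnames = list("a", "a"))),
                 "two features")
})

test_that("AUC integrates the CDF stepwise and is 1 exactly for perfectly consistent matrices", {
    # two-point {0,1} distribution: the perfectly consistent case
    M <- .consensusOf(c(0, 0, 0, 1, 1, 1), 4)
    expect_identical(consensusAUC(M), 1)

    # equal thirds at 0, 0.5, 1
    M <- .consensusOf(c(0, 0.5, 1), 3)
    expect_equal(consensusAUC(M), 0.5 * (2 / 3) + 0.5 * 1)

    # random matrices match the summation oracle
    set.seed(9)
    for (rep in 1:5) {
        M <- randomConsensusMatrix(6)
        expect_equal(consensusAUC(M), naiveAUC(M), tolerance = 1e-12)
    }

    # intermediate values strictly below 1 pull the AUC below 1
    M <- .consensusOf(c(0, 0.6, 1, 0, 0.6, 1), 4)
    expect_lt(consensusAUC(M), 1)

    # degenerate single-valued CDF: empty sum
    M <- .consensusOf(rep(0.5, 3), 3)
    expect_warning(a <- consensusAUC(M), "degenerate")
    expect_identical(a, 0)
})

test_that("delta-K follows its two definitions", {
    auc <- c(`2` = 0.5, `3` = 0.9, `4` = 0.92)

    d <- deltaK(auc, definition = "difference")
    expect_equal(d@deltaK, c(NA, 0.4, 0.02))
    expect_equal(estimateK(d), 3L, ignore_attr = TRUE)

    r <- deltaK(auc, definition = "relative")
    expect_equal(r@deltaK, c(0.5, 0.8, 0.02 / 0.9), tolerance = 1e-12)
    expect_equal(estimateK(r), 3L, ignore_attr = TRUE)

    expect_warning(deltaK(c(`2` = 0.5, `4` = 0.9)), "non-contiguous")
    expect_warning(deltaK(c(`2` = 0, `3` = 0.5)), "undefined")
    expect_error(deltaK(c(`2` = 0.5)), "at least two")
})

test_that("the cluster number estimate picks the highest interior peak with deterministic tie-breaks", {
    # a rising right edge is not a peak: the interior peak wins even when
    # the curve ends higher
    p <- deltaK(c(`2` = 1, `3` = 0.63, `4` = 0.66, `5` = 0.78, `6` = 0.79,
                  `7` = 1.0), definition = "relative")
    est <- estimateK(p)
    expect_equal(est, 5L, ignore_attr = TRUE)
    expect_identical(attr(est, "flag"), "peak")

    # tie between two peaks resolves toward smaller k
    tie <- new("DeltaKProfile", k = 2:7,
               auc = rep(NA_real_, 6),
               deltaK = c(0.05, 0.1, 0.4, 0.1, 0.4, 0.1),
               definition = "relative", source = "x")
    expect_equal(estimateK(tie), 4L, ignore_attr = TRUE)

    # flat profile: fall back to the smallest evaluated k, flagged
    flat <- deltaK(c(`2` = 0.7, `3` = 0.7, `4` = 0.7),
                   definition = "difference")
    est <- estimateK(flat)
    expect_equal(est, 2L, ignore_attr = TRUE)
    expect_identical(attr(est, "flag"), "flat")

    # monotone rising profile: no peak, argmax fallback is flagged
    mono <- deltaK(c(`2` = 0.2, `3` = 0.4, `4` = 0.9),
                   definition = "difference")
    est <- estimateK(mono)
    expect_identical(attr(est, "flag"), "no-peak")
    expect_equal(est, 4L, ignore_attr = TRUE)

    # all-NA candidates: no-estimate sentinel
    bad <- new("DeltaKProfile", k = 2:4, auc = rep(NA_real_, 3),
               deltaK = c(0.5, NA, NA), definition = "relative",
               source = "x")
    expect_warning(est <- estimateK(bad), "no defined candidate")
    expect_identical(est, NA_integer_, ignore_attr = TRUE)
})

test_that("appending pure noise conditions weakly lowers the AUC at the true cluster number", {
    aucSignal <- aucNoise <- numeric(0)
    for (s in 1:5) {
        sim <- simulateProfiles(nPerProfile = 8, sigma = 0.05, seed = s,
                                spikeCounts = c(0, 0, 0, 0))
        x <- asExpressionMatrix(sim)
        set.seed(s)
        noisy <- cbind(x, matrix(rnorm(nrow(x) * 4, 0, 1), nrow(x),
                                 dimnames = list(NULL, paste0("n", 1:4))))
        aucSignal[s] <- consensusAUC(
            consensusCluster(x, algorithmSpec("pam"), k = 4,
                             iterations = 30, seed = s))
        aucNoise[s] <- consensusAUC(
            consensusCluster(noisy, algorithmSpec("pam"), k = 4,
                             iterations = 30, seed = s))
    }
    expect_lte(mean(aucNoise), mean(aucSignal))
})
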