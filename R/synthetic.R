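## The four base expression shapes and the four deviant "spike" shapes of
## the validation simulation, over four conditions. Note that spike shape 3
## coincides with base profile 3 by construction; it is recorded as a spike
## regardless, which makes it the mildest outlier class.
.baseProfiles <- rbind(
    c(1, 0, 1, 1),
    c(0, 1, 1, 0),
    c(1, 1, 0, 0),
    c(0, 1, 0, 0)
)

.spikeProfiles <- rbind(
    c(1, 1, 1, 1),
    c(0, 0, 1, 1),
    c(1, 1, 0, 0),
    c(0.5, 0.5, 0, 0)
)

#' Centre profiles of the synthetic expression simulation
#'
#' @return a list with matrices `base` (four base profiles) and `spike`
#'   (four deviant spike profiles), each 4 shapes x 4 conditions.
#' @export
simulationProfiles <- function() {
    list(base = .baseProfiles, spike = .spikeProfiles)
}

#' Simulate spiked expression-profile data
#'
#' Generates a synthetic gene expression matrix over four conditions:
#' rows drawn from normal distributions centred on four characteristic
#' base profiles, spiked with rows centred on four deviant shapes. The
#' defaults produce the standard validation set of 120 genes (25 per base
#' profile plus 5 per spike shape), with noise standard deviation 0.1 --
#' small against the unit separation of the centre profiles, so the base
#' groups are well separated while spike rows remain ambiguous. Identical
#' parameters and seed reproduce the matrix bitwise.
#'
#' Every feature carries ground truth: generating profile, spike status,
#' spike shape, and for spike rows also the nearest base profile by
#' Euclidean distance between centres (ties toward the lower profile
#' index). Spike shape 3 equals base profile 3, so those rows are
#' indistinguishable from base rows by construction.
#'
#' @param nPerProfile rows per base profile; default 25.
#' @param sigma noise standard deviation (applied i.i.d. per condition);
#'   default 0.1.
#' @param seed generator seed.
#' @param spikeCounts integer vector of rows per spike shape; default
#'   `c(5, 5, 5, 5)`.
#' @return a [SummarizedExperiment::SummarizedExperiment-class] whose
#'   first assay is the features x conditions matrix and whose `rowData`
#'   holds the truth columns `profile` (base profile index; for spike rows
#'   the nearest base), `is_spike` and `spike_shape` (NA for base rows).
#'   `metadata()` records `sigma`, `seed`, `nPerProfile` and
#'   `spikeCounts`.
#' @examples
#' sim <- simulateProfiles(seed = 42)
#' dim(sim)                                   # 120 x 4
#' table(SummarizedExperiment::rowData(sim)$is_spike)
#' @export
simulateProfiles <- function(nPerProfile = 25L, sigma = 0.1, seed = 1L,
                             spikeCounts = c(5L, 5L, 5L, 5L)) {
    nPerProfile <- as.integer(nPerProfile)
    spikeCounts <- as.integer(spikeCounts)
    if (length(spikeCounts) != nrow(.spikeProfiles))
        stop("'spikeCounts' must give one count per spike shape")
    if (nPerProfile < 0L || any(spikeCounts < 0L))
        stop("row counts must be nonnegative")
    if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
        stop("'sigma' must be a single nonnegative value")

    baseIdx <- rep(seq_len(nrow(.baseProfiles)), each = nPerProfile)
    spikeIdx <- rep(seq_len(nrow(.spikeProfiles)), times = spikeCounts)
    centres <- rbind(.baseProfiles[baseIdx, , drop = FALSE],
                     .spikeProfiles[spikeIdx, , drop = FALSE])
    n <- nrow(centres)
    if (n < 1L)
        stop("no rows requested")

    set.seed(as.integer(seed))
    x <- centres + matrix(stats::rnorm(n * ncol(centres), 0, sigma),
                          n, ncol(centres))
    rownames(x) <- sprintf("gene_%03d", seq_len(n))
    colnames(x) <- paste0("condition_", seq_len(ncol(centres)))

    nearestBase <- apply(.spikeProfiles, 1L, function(s) {
        which.min(colSums((t(.baseProfiles) - s)^2))
    })
    truth <- S4Vectors::DataFrame(
        profile = c(baseIdx, nearestBase[spikeIdx]),
        is_spike = rep(c(FALSE, TRUE), c(length(baseIdx), length(spikeIdx))),
        spike_shape = c(rep(NA_integer_, length(baseIdx)), spikeIdx),
        row.names = rownames(x)
    )
    SummarizedExperiment::SummarizedExperiment(
        assays = list(expression = x),
        rowData = truth,
        metadata = list(sigma = sigma, seed = as.integer(seed),
                        nPerProfile = nPerProfile,
                        spikeCounts = spikeCounts)
    )
}
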