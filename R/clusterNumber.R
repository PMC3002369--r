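#' Empirical CDF of consensus values
#'
#' Computes the cumulative distribution of the off-diagonal (i < j)
#' entries of a consensus-type matrix: CDF(c) is the fraction of the
#' N(N-1)/2 feature pairs whose consensus is at most c, evaluated at each
#' distinct entry value. The diagonal is excluded throughout.
#'
#' @param M a [ConsensusResult-class], [MergeResult-class] or plain
#'   consensus-type matrix with at least two features.
#' @return a [ConsensusCDF-class].
#' @examples
#' M <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' diag(M) <- 1
#' cc <- consensusCDF(M)
#' cc@values  # 0.5
#' cc@cdf     # 1
#' @export
consensusCDF <- function(M) {
    m <- consensusMatrix(M)
    if (nrow(m) < 2L)
        stop("a consensus CDF needs at least two features")
    v <- m[upper.tri(m)]
    xs <- sort(unique(v))
    counts <- tabulate(match(v, xs), nbins = length(xs))
    new("ConsensusCDF", values = xs, cdf = cumsum(counts) / length(v),
        nPairs = as.integer(length(v)))
}

#' @describeIn consensusAUC stepwise integral of a consensus CDF.
#' @export
setMethod("consensusAUC", "ConsensusCDF", function(x) {
    if (length(x@values) < 2L) {
        warning("degenerate CDF with a single distinct value; AUC = 0 ",
                "by the empty-sum convention")
        return(0)
    }
    sum(diff(x@values) * x@cdf[-1L])
})

#' @describeIn consensusAUC compute the CDF first, then its AUC.
#' @export
setMethod("consensusAUC", "ANY", function(x) {
    consensusAUC(consensusCDF(x))
})

#' Change in AUC across cluster numbers
#'
#' Builds a delta-K profile from per-k AUC values. Under the default
#' `"relative"` definition the first entry is seeded with AUC(k_min) and
#' subsequent entries are (AUC(k) - AUC(k-1)) / AUC(k-1); under
#' `"difference"` the first entry is NA and subsequent entries are plain
#' AUC(k) - AUC(k-1). The true cluster number shows up as a peak of this
#' curve (see [estimateK()]). A non-contiguous k grid is accepted with a
#' warning; deltas are then taken between adjacent evaluated points. A
#' zero AUC(k-1) under the relative definition yields an NA entry with a
#' warning.
#'
#' @param auc numeric vector of AUC values; either named by k or
#'   accompanied by `k`.
#' @param k integer vector of evaluated cluster numbers (ascending).
#' @param definition `"relative"` (default) or `"difference"`.
#' @param source descriptor of the matrix family (algorithm name or
#'   `"merge"`).
#' @return a [DeltaKProfile-class].
#' @examples
#' p <- deltaK(c(`2` = 0.5, `3` = 0.9, `4` = 0.92),
#'             definition = "difference")
#' p@deltaK   # NA 0.40 0.02
#' estimateK(p)
#' @export
deltaK <- function(auc, k = NULL, definition = c("relative", "difference"),
                   source = "consensus") {
    definition <- match.arg(definition)
    if (is.null(k)) {
        if (is.null(names(auc)))
            stop("supply 'k' or name the AUC values by cluster number")
        k <- as.integer(names(auc))
    }
    k <- as.integer(k)
    if (length(k) != length(auc))
        stop("'k' and 'auc' must align")
    if (length(k) < 2L)
        stop("at least two consecutive cluster numbers are required")
    ord <- order(k)
    k <- k[ord]
    auc <- unname(auc[ord])
    if (any(diff(k) != 1L))
        warning("non-contiguous cluster number grid; delta-K computed ",
                "between adjacent evaluated points")
    prev <- auc[-length(auc)]
    if (definition == "relative") {
        dk <- c(auc[1L], (auc[-1L] - prev) / prev)
        if (any(prev == 0, na.rm = TRUE)) {
            warning("AUC of 0 at the preceding cluster number; relative ",
                    "delta-K undefined there (NA)")
            dk[c(FALSE, prev == 0)] <- NA_real_
        }
    } else {
        dk <- c(NA_real_, auc[-1L] - prev)
    }
    new("DeltaKProfile", k = k, auc = auc, deltaK = dk,
        definition = definition, source = source)
}

#' @describeIn estimateK peak detection on a delta-K profile.
#' @export
setMethod("estimateK", "DeltaKProfile", function(profile) {
    dk <- profile@deltaK
    k <- profile@k
    n <- length(dk)
    cand <- 2:n    # the first entry is the seed value (or NA), never a peak
    vals <- dk[cand]
    if (all(is.na(vals))) {
        warning("delta-K profile has no defined candidate entries")
        out <- NA_integer_
        attr(out, "flag") <- "undefined"
        return(out)
    }
    low <- min(vals, na.rm = TRUE) - 1
    padded <- ifelse(is.na(dk), low, dk)
    isPeak <- vapply(cand, function(i) {
        i < n && padded[i] > padded[i - 1L] && padded[i] > padded[i + 1L]
    }, logical(1))
    if (any(isPeak)) {
        peaks <- cand[isPeak]
        best <- peaks[which.max(padded[peaks])]   # which.max ties -> first
        out <- k[best]
        attr(out, "flag") <- "peak"
        return(out)
    }
    if (diff(range(vals, na.rm = TRUE)) == 0) {
        out <- k[1L]
        attr(out, "flag") <- "flat"
        return(out)
    }
    out <- k[cand[which.max(padded[cand])]]
    attr(out, "flag") <- "no-peak"
    out
})

setMethod("show", "ConsensusCDF", function(object) {
    cat("ConsensusCDF over", object@nPairs, "feature pairs,",
        length(object@values), "distinct values\n")
})

setMethod("show", "DeltaKProfile", function(object) {
    cat("DeltaKProfile (", object@source, ", ", object@definition,
        " definition)\n", sep = "")
    print(data.frame(k = object@k, auc = round(object@auc, 4),
                     deltaK = round(object@deltaK, 4)), row.names = FALSE)
    est <- suppressWarnings(estimateK(object))
    cat("  estimated k:", est, "(", attr(est, "flag"), ")\n")
})
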