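## Diagnostic plots, base graphics. Outliers on the robustness boxplots are
## marked with open triangles using the standard 1.5 x IQR whisker rule.

#' Membership robustness boxplots per cluster
#'
#' One box per reference cluster showing the distribution of membership
#' robustness, with outliers (beyond 1.5 x IQR from the box) overplotted
#' as open triangles. Empty panels cannot arise (every non-empty cluster
#' has members); singleton clusters appear as a single point.
#'
#' @param report a [RobustnessReport-class].
#' @param main plot title.
#' @return invisibly, the list of outlier feature identifiers per cluster.
#' @export
plotMembershipRobustness <- function(report,
                                     main = paste("Membership robustness,",
                                                  report@source)) {
    df <- report@membership
    groups <- split(df$membership_robustness, df$cluster)
    bp <- graphics::boxplot(groups, outline = FALSE, ylim = c(0, 1),
                            xlab = "cluster",
                            ylab = "membership robustness", main = main,
                            range = 1.5)
    outliers <- lapply(names(groups), function(cl) {
        v <- groups[[cl]]
        q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
        lim <- 1.5 * (q[2] - q[1])
        out <- v < q[1] - lim | v > q[2] + lim
        if (any(out)) {
            graphics::points(rep(match(cl, names(groups)), sum(out)),
                             v[out], pch = 2)
        }
        df$feature_id[df$cluster == as.integer(cl)][out]
    })
    names(outliers) <- names(groups)
    invisible(outliers)
}

#' Mean expression profile per cluster
#'
#' Plots, for each cluster of an assignment, the mean expression across
#' features against condition, one panel per cluster. Empty clusters are
#' skipped with an annotation in the panel title space.
#'
#' @param data the expression matrix the assignment was computed from.
#' @param assignment a [ClusterAssignment-class].
#' @return invisibly, the matrix of cluster mean profiles.
#' @export
plotClusterProfiles <- function(data, assignment) {
    x <- asExpressionMatrix(data)
    sets <- clusterIndexSets(assignment)
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(sets)),
                         mar = c(3, 3, 2, 1))
    on.exit(graphics::par(old))
    means <- matrix(NA_real_, length(sets), ncol(x),
                    dimnames = list(names(sets), colnames(x)))
    for (cl in names(sets)) {
        sub <- x[sets[[cl]], , drop = FALSE]
        means[cl, ] <- colMeans(sub)
        graphics::matplot(t(sub), type = "l", lty = 1,
                          col = grDevices::grey(0.7),
                          xlab = "condition", ylab = "expression",
                          main = paste0("cluster ", cl, " (n=",
                                        nrow(sub), ")"))
        graphics::lines(means[cl, ], lwd = 2)
    }
    invisible(means)
}

#' Delta-K plot
#'
#' Overlays the delta-K curves of several sources (one per algorithm plus
#' the merge) against cluster number; the peak of a curve estimates the
#' cluster number best supported by that source.
#'
#' @param profiles a [DeltaKProfile-class] or a list of them.
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plotDeltaK <- function(profiles, main = "delta-K") {
    if (is(profiles, "DeltaKProfile"))
        profiles <- list(profiles)
    allK <- sort(unique(unlist(lapply(profiles, function(p) p@k))))
    allV <- unlist(lapply(profiles, function(p) p@deltaK))
    graphics::plot(NA, xlim = range(allK), ylim = range(allV, na.rm = TRUE),
                   xlab = "cluster number k", ylab = expression(Delta * K),
                   main = main, xaxt = "n")
    graphics::axis(1, at = allK)
    for (i in seq_along(profiles)) {
        p <- profiles[[i]]
        graphics::lines(p@k, p@deltaK, col = i, lty = i, type = "b",
                        pch = i)
    }
    graphics::legend("topright",
                     legend = vapply(profiles, function(p) p@source,
                                     character(1)),
                     col = seq_along(profiles), lty = seq_along(profiles),
                     pch = seq_along(profiles), bty = "n")
    invisible(NULL)
}

#' Consensus matrix heatmap
#'
#' Displays a consensus-type matrix as an image with features ordered by
#' the reference clustering (when available), so stable clusters appear
#' as dark blocks on the diagonal.
#'
#' @param M a [ConsensusResult-class], [MergeResult-class] or plain
#'   consensus-type matrix.
#' @param reference optional [ClusterAssignment-class] used to order the
#'   features; defaults to the result's own reference when present.
#' @param main plot title.
#' @return invisibly, the row order used.
#' @export
plotConsensusHeatmap <- function(M, reference = NULL,
                                 main = "consensus matrix") {
    m <- consensusMatrix(M)
    if (is.null(reference) && is(M, "ConsensusResult"))
        reference <- referenceClustering(M)
    ord <- if (!is.null(reference))
        order(reference@labels[rownames(m)]) else seq_len(nrow(m))
    m <- m[ord, ord]
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)),
                    t(m[rev(seq_len(nrow(m))), ]),
                    col = grDevices::grey(seq(1, 0, length.out = 64)),
                    xlab = "", ylab = "", axes = FALSE, main = main)
    graphics::box()
    invisible(ord)
}

#' Write all plots for an experiment bundle
#'
#' For each consensus cell: a membership-robustness boxplot figure, a
#' cluster mean-profile figure and a consensus heatmap; for each merge, a
#' heatmap; plus a single delta-K figure overlaying every source.
#'
#' @param bundle a [ConsensusExperiment-class].
#' @param dir output directory for PNG files.
#' @param data the (preprocessed) expression matrix, needed for the
#'   profile plots; omit to skip them.
#' @param width,height device size in pixels.
#' @return invisibly, the paths written.
#' @export
makePlots <- function(bundle, dir, data = NULL, width = 900, height = 700) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    dev <- function(name) {
        p <- file.path(dir, paste0(name, ".png"))
        grDevices::png(p, width = width, height = height)
        paths <<- c(paths, p)
        p
    }
    for (nm in names(bundle@robustness)) {
        dev(paste0(nm, ".membership"))
        plotMembershipRobustness(bundle@robustness[[nm]])
        grDevices::dev.off()
    }
    for (nm in names(bundle@consensus)) {
        res <- bundle@consensus[[nm]]
        dev(paste0(nm, ".heatmap"))
        plotConsensusHeatmap(res, main = nm)
        grDevices::dev.off()
        if (!is.null(data)) {
            dev(paste0(nm, ".profiles"))
            plotClusterProfiles(data, referenceClustering(res))
            grDevices::dev.off()
        }
    }
    for (nm in names(bundle@merges)) {
        dev(paste0("merge.", nm, ".heatmap"))
        plotConsensusHeatmap(bundle@merges[[nm]], main = paste("merge", nm))
        grDevices::dev.off()
    }
    if (length(bundle@deltaK)) {
        dev("delta_k")
        plotDeltaK(bundle@deltaK)
        grDevices::dev.off()
    }
    invisible(paths)
}
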