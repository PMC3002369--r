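## Registry of clustering backends. Every backend is a function
## (x, k, spec) -> cluster labels, where x is either a numeric matrix
## (features x conditions) or a "dist" object, and the returned labels are
## an integer/numeric vector with one entry per feature, either named by
## feature identifier or given in row order. runClustering() canonicalises
## and validates the output, so backends stay minimal.

.algorithmRegistry <- new.env(parent = emptyenv())

#' Register a clustering backend
#'
#' Adds a clustering algorithm to the registry under a unique name so that
#' [runClustering()] and the resampling engine can use it. The runner must
#' accept `(x, k, spec)` -- a numeric matrix (or `dist` object), the
#' requested cluster count, and the [AlgorithmSpec-class] -- and return one
#' cluster label per feature, named by feature identifier or in row order.
#' Runner output is validated at first use, not at registration.
#'
#' @param name unique registry name.
#' @param runner the backend function.
#' @return the name, invisibly.
#' @examples
#' registerAlgorithm("rowsplit", function(x, k, spec) {
#'     rep_len(seq_len(k), nrow(as.matrix(x)))
#' })
#' "rowsplit" %in% listAlgorithms()
#' @export
registerAlgorithm <- function(name, runner) {
    stopifnot(is.character(name), length(name) == 1L, nzchar(name))
    if (!is.function(runner))
        stop("'runner' must be a function(x, k, spec)")
    if (exists(name, envir = .algorithmRegistry, inherits = FALSE))
        stop("algorithm '", name, "' is already registered")
    assign(name, runner, envir = .algorithmRegistry)
    invisible(name)
}

#' List registered clustering backends
#'
#' @return a character vector of registry names.
#' @export
listAlgorithms <- function() {
    sort(ls(.algorithmRegistry))
}

.getAlgorithm <- function(name) {
    if (!exists(name, envir = .algorithmRegistry, inherits = FALSE))
        stop("unknown clustering algorithm '", name, "'; registered: ",
             paste(listAlgorithms(), collapse = ", "))
    get(name, envir = .algorithmRegistry, inherits = FALSE)
}

#' Construct an algorithm specification
#'
#' @param algorithm registry name of the backend. Built-ins:
#'   `"hierarchical"` (agglomerative, via [stats::hclust()]), `"kmeans"`
#'   (via [stats::kmeans()]) and `"pam"` (k-medoids, classical PAM
#'   BUILD+SWAP via [cluster::pam()]).
#' @param distance distance metric; default `"euclidean"`.
#' @param linkage linkage for hierarchical backends; default `"average"`
#'   (the agglomerative-nesting default), `"complete"`, `"single"` and
#'   `"ward.D2"` selectable.
#' @param params named list of extra parameters. The k-means backend
#'   understands `variant` (`"Hartigan-Wong"`, `"MacQueen"` or `"Lloyd"`),
#'   `nstart` (default 10) and `iterMax` (default 50).
#' @return an [AlgorithmSpec-class].
#' @examples
#' algorithmSpec("kmeans", params = list(variant = "MacQueen"))
#' @export
algorithmSpec <- function(algorithm = "hierarchical", distance = "euclidean",
                          linkage = "average", params = list()) {
    new("AlgorithmSpec", algorithm = algorithm, distance = distance,
        linkage = linkage, params = params)
}

.param <- function(spec, name, default) {
    if (!is.null(spec@params[[name]])) spec@params[[name]] else default
}

## ---- built-in backends ----------------------------------------------------

.runHierarchical <- function(x, k, spec) {
    d <- if (inherits(x, "dist")) x else
        stats::dist(x, method = spec@distance)
    stats::cutree(stats::hclust(d, method = spec@linkage), k = k)
}

## Consensus resampling presumes backends whose output is a deterministic
## function of the data; a single random restart of k-means reports an
## arbitrary local optimum, so multiple seeded restarts are the default.
.runKmeans <- function(x, k, spec) {
    if (inherits(x, "dist"))
        stop("the k-means backend requires coordinate data, ",
             "not a precomputed dissimilarity")
    stats::kmeans(x, centers = k,
                  algorithm = .param(spec, "variant", "Hartigan-Wong"),
                  nstart = .param(spec, "nstart", 10L),
                  iter.max = .param(spec, "iterMax", 50L))$cluster
}

.runPam <- function(x, k, spec) {
    if (inherits(x, "dist"))
        cluster::pam(x, k = k, diss = TRUE, cluster.only = TRUE)
    else
        cluster::pam(x, k = k, metric = spec@distance, cluster.only = TRUE)
}

.registerBuiltins <- function() {
    for (nm in c("hierarchical", "kmeans", "pam"))
        if (exists(nm, envir = .algorithmRegistry, inherits = FALSE))
            rm(list = nm, envir = .algorithmRegistry)
    registerAlgorithm("hierarchical", .runHierarchical)
    registerAlgorithm("kmeans", .runKmeans)
    registerAlgorithm("pam", .runPam)
}

## ---- running a backend ----------------------------------------------------

.featureIdsOf <- function(x) {
    if (inherits(x, "dist")) attr(x, "Labels") else rownames(x)
}

.nFeaturesOf <- function(x) {
    if (inherits(x, "dist")) attr(x, "Size") else nrow(x)
}

#' Run a clustering backend
#'
#' Looks up the backend named in `spec`, seeds the RNG, runs it on the data
#' and returns a validated, canonicalised [ClusterAssignment-class].
#' Labels are renumbered by order of first appearance in row order, so the
#' assignment is stable across runs and label permutations. Rerunning with
#' identical data, spec and seed yields identical labels for every
#' built-in backend.
#'
#' @param data a numeric features x conditions matrix with unique row
#'   identifiers (or anything [asExpressionMatrix()] accepts), or a `dist`
#'   object for backends that take a precomputed dissimilarity
#'   (hierarchical and pam).
#' @param k requested number of clusters, between 2 and the number of
#'   features.
#' @param spec an [AlgorithmSpec-class].
#' @param seed RNG seed consumed by stochastic backends.
#' @return a [ClusterAssignment-class].
#' @examples
#' x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 5), 10))
#' rownames(x) <- paste0("f", 1:20)
#' table(clusterLabels(runClustering(x, 2, algorithmSpec("pam"))))
#' @export
runClustering <- function(data, k, spec = algorithmSpec(), seed = 1L) {
    if (!inherits(data, "dist")) {
        data <- asExpressionMatrix(data)
        if (!all(is.finite(data)))
            stop("data contains missing or non-finite values")
    }
    n <- .nFeaturesOf(data)
    ids <- .featureIdsOf(data)
    if (is.null(ids))
        stop("data must carry unique feature identifiers (row names)")
    k <- as.integer(k)
    if (length(k) != 1L || is.na(k) || k < 2L)
        stop("'k' must be a single integer >= 2")
    if (k > n)
        stop("'k' (", k, ") exceeds the number of features (", n, ")")
    runner <- .getAlgorithm(spec@algorithm)
    set.seed(seed)
    raw <- runner(data, k, spec)
    .asClusterAssignment(raw, ids, k, spec)
}

## Validates runner output against the contract and canonicalises labels.
.asClusterAssignment <- function(raw, ids, k, spec) {
    if (is(raw, "ClusterAssignment"))
        raw <- raw@labels
    if (!is.numeric(raw) && !is.integer(raw))
        stop("backend '", spec@algorithm,
             "' violated the runner contract: labels must be numeric")
    if (!is.null(names(raw))) {
        if (!setequal(names(raw), ids))
            stop("backend '", spec@algorithm, "' violated the runner ",
                 "contract: labels must cover every feature exactly once")
        raw <- raw[ids]
    } else if (length(raw) != length(ids)) {
        stop("backend '", spec@algorithm, "' violated the runner contract: ",
             length(raw), " labels for ", length(ids), " features")
    }
    if (anyNA(raw))
        stop("backend '", spec@algorithm,
             "' violated the runner contract: NA labels")
    canon <- match(raw, unique(raw))
    if (max(canon) > k)
        stop("backend '", spec@algorithm, "' violated the runner contract: ",
             max(canon), " distinct labels for k = ", k)
    labels <- as.integer(canon)
    names(labels) <- ids
    new("ClusterAssignment", labels = labels, k = k, algorithm = spec)
}

## ---- ClusterAssignment accessors ------------------------------------------

#' @describeIn ClusterAssignment labels named by feature identifier.
#' @param x a `ClusterAssignment`.
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @describeIn ClusterAssignment member identifiers per non-empty cluster.
#' @export
setMethod("clusterIndexSets", "ClusterAssignment", function(x) {
    split(names(x@labels), x@labels)
})

#' @describeIn ClusterAssignment member counts per non-empty cluster.
#' @export
setMethod("clusterSizes", "ClusterAssignment", function(x) {
    tab <- table(x@labels)
    stats::setNames(as.integer(tab), names(tab))
})

setMethod("show", "ClusterAssignment", function(object) {
    sz <- clusterSizes(object)
    cat("ClusterAssignment:", length(object@labels), "features,",
        "k =", object@k, "(", length(sz), "non-empty )\n")
    cat("  algorithm:", object@algorithm@algorithm,
        "| sizes:", paste(sz, collapse = ", "), "\n")
})

setMethod("show", "AlgorithmSpec", function(object) {
    cat("AlgorithmSpec:", object@algorithm,
        "| distance:", object@distance,
        if (object@algorithm == "hierarchical")
            paste("| linkage:", object@linkage) else "", "\n")
    if (length(object@params))
        cat("  params:", paste(names(object@params),
            vapply(object@params, format, ""), sep = "=", collapse = ", "),
            "\n")
})
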