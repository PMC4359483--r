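#' @import methods
NULL

#' Binary marker matrix with missing-value mask
#'
#' Container for an N x M matrix of binary evolutionary markers: rows are
#' observed sequences (bisulfite reads collapsed to methylation patterns) or
#' single cells, columns are marker sites (CpG sites or SNV loci). Entries are
#' 0/1 or \code{NA} for missing (e.g. allele dropout in single-cell data).
#' For SNV data, 1 encodes a heterozygous mutation and 0 the wild-type allele.
#'
#' @slot values integer matrix with entries in \{0, 1, NA\}.
#' @slot kind character, either \code{"methylation"} or \code{"snv"}.
#'
#' @examples
#' mm <- MarkerMatrix(matrix(c(1, 0, 0, NA), 2, 2), kind = "methylation")
#' missingMask(mm)
#' @export
setClass("MarkerMatrix",
    representation(values = "matrix", kind = "character"))

setValidity("MarkerMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("'values' must be a numeric matrix")
    ok <- is.na(v) | v == 0 | v == 1
    if (!all(ok))
        return("all non-missing entries must be 0 or 1")
    if (length(object@kind) != 1L ||
        !object@kind %in% c("methylation", "snv"))
        return("'kind' must be \"methylation\" or \"snv\"")
    TRUE
})

#' Construct a MarkerMatrix
#'
#' @param values numeric matrix with entries in \{0, 1, NA\}.
#' @param kind \code{"methylation"} or \code{"snv"}.
#' @return A \code{\linkS4class{MarkerMatrix}} object.
#' @export
MarkerMatrix <- function(values, kind = c("methylation", "snv")) {
    kind <- match.arg(kind)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("MarkerMatrix", values = values, kind = kind)
}

#' Instantiated portion of a tree-structured stick-breaking process
#'
#' The finite, instantiated part of the infinite clone tree. Each node is
#' addressed by a clone label (a sequence of positive integers; the root is
#' the empty sequence) and stores its depth-wise stick variable \code{nu},
#' the breadth-wise sticks \code{psi} of its instantiated children, the
#' real-valued clone parameter vector \code{theta} (one entry per marker
#' site), the branch length \code{t} to its parent (absent for the root) and
#' the indices of observations assigned to it.
#'
#' Nodes are stored in a prefix-closed named list keyed by the dot-joined
#' label path with a leading \code{"0"} for the root (root key \code{"0"},
#' the second child of the first child has key \code{"0.1.2"}).
#'
#' @slot nodes named list of node records (fields \code{path}, \code{nu},
#'   \code{psi}, \code{theta}, \code{t}, \code{assigned}).
#' @slot hypers list with elements \code{lambda}, \code{alpha0}, \code{gamma}.
#' @export
setClass("TssbTree", representation(nodes = "list", hypers = "list"))

setValidity("TssbTree", function(object) {
    nd <- object@nodes
    if (length(nd) == 0L) return("tree must contain at least the root node")
    keys <- names(nd)
    if (is.null(keys) || anyDuplicated(keys))
        return("nodes must be uniquely named by label key")
    if (!"0" %in% keys) return("root node (key \"0\") missing")
    for (k in keys) {
        n <- nd[[k]]
        if (!identical(labelKey(n$path), k))
            return(sprintf("node key '%s' does not match its path", k))
        if (length(n$path) > 0L && !labelKey(parentLabel(n$path)) %in% keys)
            return(sprintf("node '%s' lacks its parent (tree not prefix-closed)", k))
        if (n$nu < 0 || n$nu > 1) return("nu outside [0,1]")
        if (length(n$psi) && (any(n$psi < 0) || any(n$psi > 1)))
            return("psi outside [0,1]")
        if (length(n$path) > 0L && (is.na(n$t) || n$t < 0))
            return("non-root nodes need a nonnegative branch length")
    }
    h <- object@hypers
    if (!all(c("lambda", "alpha0", "gamma") %in% names(h)))
        return("hypers must contain lambda, alpha0, gamma")
    if (h$alpha0 <= 0 || h$gamma <= 0 || h$lambda <= 0)
        return("hyperparameters must be positive")
    TRUE
})

#' Ground-truth simulation fixture
#'
#' A finite clone tree with known clone frequencies and per-clone binary
#' marker patterns, used as the generating truth of the simulation benchmark.
#'
#' @slot mode evolution mode, one of \code{"monoclonal"},
#'   \code{"polyclonal_low"}, \code{"polyclonal_medium"},
#'   \code{"polyclonal_high"}, \code{"mutator"}.
#' @slot labels list of integer clone label paths (root = empty path).
#' @slot frequencies numeric clone frequencies summing to one.
#' @slot genotypes binary matrix, one row per clone, one column per site.
#' @export
setClass("CloneFixture",
    representation(mode = "character", labels = "list",
                   frequencies = "numeric", genotypes = "matrix"))

setValidity("CloneFixture", function(object) {
    k <- length(object@labels)
    if (length(object@frequencies) != k || nrow(object@genotypes) != k)
        return("labels, frequencies and genotypes must agree in length")
    if (abs(sum(object@frequencies) - 1) > 1e-8)
        return("clone frequencies must sum to 1")
    if (any(object@frequencies < 0))
        return("clone frequencies must be nonnegative")
    if (!all(object@genotypes %in% c(0, 1)))
        return("genotypes must be binary")
    TRUE
})

#' MCMC trace of the clone-tree posterior
#'
#' Ordered retained samples from \code{\link{runMcmc}}. Each snapshot records
#' the per-observation clone assignments, the instantiated tree (labels,
#' weights, parameters, branch lengths), the complete-data log-likelihood
#' with assignments marginalised out, and the big-node count (number of
#' clones with weight above 0.01).
#'
#' @slot snapshots list of per-sample snapshots.
#' @slot nObs number of observations.
#' @slot kind marker kind of the data.
#' @slot config the \code{\link{mcmcConfig}} used.
#' @export
setClass("McmcTrace",
    representation(snapshots = "list", nObs = "numeric",
                   kind = "character", config = "list"))

#' Baseline clustering and spanning-tree fit
#'
#' Result of the distance-based baseline pipeline: Jaccard distances,
#' silhouette-selected clustering, estimated per-clone marker patterns
#' (methyltypes) and a rooted Hamming minimum spanning tree over clones.
#'
#' @slot method \code{"hierarchical"} or \code{"k_centroids"}.
#' @slot labels integer cluster assignment per observation.
#' @slot methyltypes binary matrix, one row per cluster.
#' @slot edges two-column integer matrix of directed tree edges
#'   (parent, child), empty for a single cluster.
#' @slot root integer index of the root cluster.
#' @export
setClass("BaselineFit",
    representation(method = "character", labels = "integer",
                   methyltypes = "matrix", edges = "matrix", root = "integer"))

## ---- basic accessors ----

#' @describeIn MarkerMatrix-class the underlying 0/1/NA matrix.
#' @param x,object a \code{MarkerMatrix}.
#' @export
markerValues <- function(x) x@values

#' @describeIn MarkerMatrix-class logical matrix, TRUE where the entry is
#'   missing.
#' @export
missingMask <- function(x) is.na(x@values)

#' @describeIn MarkerMatrix-class marker kind (\code{"methylation"} or
#'   \code{"snv"}).
#' @export
markerKind <- function(x) x@kind

#' @describeIn TssbTree-class clone labels of the instantiated nodes, as a
#'   list of integer paths.
#' @param x,object a \code{TssbTree}.
#' @export
cloneLabels <- function(x) lapply(x@nodes, `[[`, "path")

#' @describeIn McmcTrace-class number of retained samples.
#' @param x,object a \code{McmcTrace}.
#' @export
nSamples <- function(x) length(x@snapshots)

#' @describeIn McmcTrace-class list of retained snapshots.
#' @export
traceSnapshots <- function(x) x@snapshots

#' @describeIn BaselineFit-class cluster labels per observation.
#' @param x,object a \code{BaselineFit}.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn BaselineFit-class per-cluster marker patterns.
#' @export
methyltypes <- function(x) x@methyltypes

setMethod("show", "MarkerMatrix", function(object) {
    v <- object@values
    cat(sprintf("MarkerMatrix: %d sequences x %d sites (%s), %.1f%% missing\n",
        nrow(v), ncol(v), object@kind, 100 * mean(is.na(v))))
})

setMethod("show", "TssbTree", function(object) {
    pi <- cloneWeights(object)
    occ <- vapply(object@nodes, function(n) length(n$assigned), integer(1))
    cat(sprintf(
        "TssbTree: %d instantiated nodes (max depth %d), %d occupied, mass %.4f\n",
        length(object@nodes),
        max(vapply(object@nodes, function(n) length(n$path), integer(1))),
        sum(occ > 0L), sum(pi)))
})

setMethod("show", "CloneFixture", function(object) {
    cat(sprintf("CloneFixture '%s': %d clones, %d sites\n",
        object@mode, length(object@labels), ncol(object@genotypes)))
})

setMethod("show", "McmcTrace", function(object) {
    cat(sprintf("McmcTrace: %d retained samples, %d observations (%s model)\n",
        length(object@snapshots), object@nObs, object@kind))
})

setMethod("show", "BaselineFit", function(object) {
    cat(sprintf("BaselineFit (%s): %d clusters, root cluster %d\n",
        object@method, nrow(object@methyltypes), object@root))
})
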