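## Evaluation: v-measure, consensus node-based shortest path tree distance,
## tree summary statistics and symmetrised Kullback-Leibler divergence of
## level-mass distributions.

#' V-measure between two partitions
#'
#' Entropy-based clustering agreement: homogeneity \eqn{h = 1 -
#' H(C_{true}|C_{pred})/H(C_{true})} measures whether each predicted cluster
#' contains members of a single true class, completeness \eqn{c = 1 -
#' H(C_{pred}|C_{true})/H(C_{pred})} whether each true class lands in a
#' single predicted cluster, and the v-measure is their harmonic mean
#' \eqn{2hc/(h+c)}, in [0, 1] with 1 for a perfect clustering. When a
#' conditioning entropy is zero the corresponding component is defined as 1.
#'
#' @param trueLabels,predLabels equal-length label vectors (any type).
#' @return The v-measure (a scalar).
#' @examples
#' vMeasure(c(1, 1, 2, 2), c("a", "a", "b", "b"))   # 1
#' @export
vMeasure <- function(trueLabels, predLabels) {
    if (length(trueLabels) != length(predLabels))
        stop("label vectors must have the same length")
    tab <- table(trueLabels, predLabels)
    n <- sum(tab)
    ent <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log(p)) }
    Ht <- ent(rowSums(tab))
    Hp <- ent(colSums(tab))
    condEnt <- function(tab) {       # H(rows | cols)
        tot <- 0
        for (j in seq_len(ncol(tab))) {
            cj <- tab[, j]
            if (sum(cj) > 0) tot <- tot + sum(cj) / n * ent(cj)
        }
        tot
    }
    h <- if (Ht == 0) 1 else 1 - condEnt(tab) / Ht
    c <- if (Hp == 0) 1 else 1 - condEnt(t(tab)) / Hp
    if (h + c == 0) return(0)
    2 * h * c / (h + c)
}

## ---- clone graphs: the common currency of the tree distance ----

#' Generic clone tree for tree comparison
#'
#' A minimal rooted-tree representation shared by the ground truth, the
#' Bayesian MAP tree and the baseline spanning trees: node identifiers,
#' undirected edges, a binary marker pattern per node and a node mass
#' (clone frequency / weight / cluster size) used to break ties when the
#' same pattern occurs at several nodes.
#'
#' @param edges two-column character matrix of node ids (may have 0 rows).
#' @param patterns binary matrix with rownames = node ids.
#' @param mass named numeric vector of node masses.
#' @return A list with class \code{"cloneGraph"}.
#' @export
cloneGraph <- function(edges, patterns, mass) {
    ids <- rownames(patterns)
    stopifnot(!is.null(ids), all(names(mass) %in% ids),
              all(as.vector(edges) %in% ids))
    structure(list(edges = edges, patterns = patterns,
                   mass = mass[ids]), class = "cloneGraph")
}

#' Coerce to a clone graph
#'
#' Methods exist for \code{\linkS4class{CloneFixture}} (true trees),
#' \code{\linkS4class{TssbTree}} (inferred Bayesian trees; node patterns are
#' the site-wise state calls of theta at threshold \code{eta}, masses the
#' clone weights) and \code{\linkS4class{BaselineFit}} (spanning trees over
#' methyltypes; masses are cluster sizes).
#'
#' @param x object to coerce.
#' @param ... further arguments (\code{eta} for \code{TssbTree}).
#' @return A \code{\link{cloneGraph}}.
#' @export
setGeneric("asCloneGraph", function(x, ...) standardGeneric("asCloneGraph"))

#' @rdname asCloneGraph
#' @export
setMethod("asCloneGraph", "CloneFixture", function(x, ...) {
    keys <- rownames(x@genotypes)
    par <- vapply(x@labels, function(p)
        if (length(p)) labelKey(parentLabel(p)) else NA_character_,
        character(1))
    has <- !is.na(par)
    cloneGraph(cbind(par[has], keys[has]), x@genotypes,
               stats::setNames(x@frequencies, keys))
})

#' @rdname asCloneGraph
#' @param eta state-call threshold for converting clone parameters to
#'   binary patterns.
#' @export
setMethod("asCloneGraph", "TssbTree", function(x, eta = 1, ...) {
    keys <- names(x@nodes)
    pats <- do.call(rbind, lapply(x@nodes, function(n)
        as.numeric(n$theta >= eta)))
    rownames(pats) <- keys
    par <- vapply(keys, function(k)
        if (k == "0") NA_character_ else parentKey(k), character(1))
    has <- !is.na(par)
    cloneGraph(cbind(par[has], keys[has]), pats, cloneWeights(x)[keys])
})

#' @rdname asCloneGraph
#' @export
setMethod("asCloneGraph", "BaselineFit", function(x, ...) {
    keys <- as.character(seq_len(nrow(x@methyltypes)))
    pats <- x@methyltypes
    rownames(pats) <- keys
    e <- x@edges
    cloneGraph(cbind(as.character(e[, 1L]), as.character(e[, 2L])), pats,
               stats::setNames(as.numeric(tabulate(x@labels, nrow(pats))),
                               keys))
})

.cloneIgraph <- function(cg) {
    ids <- rownames(cg$patterns)
    igraph::graph_from_data_frame(
        as.data.frame(cg$edges, stringsAsFactors = FALSE),
        directed = FALSE, vertices = data.frame(name = ids))
}

## map each distinct pattern string to the node carrying it with the
## largest mass
.patternNodes <- function(cg) {
    ps <- apply(cg$patterns, 1L, paste, collapse = "")
    ids <- rownames(cg$patterns)
    out <- character(0)
    for (p in unique(ps)) {
        cand <- ids[ps == p]
        out[p] <- cand[which.max(cg$mass[cand])]
    }
    out
}

#' Consensus node-based shortest path tree distance
#'
#' Compares inferred clone trees to a ground-truth tree through the marker
#' patterns their nodes carry. The shared pattern set consists of patterns
#' present in the ground truth and in every inferred tree; for each tree the
#' pairwise shortest-path (hop count) distance matrix between the nodes
#' carrying the shared patterns is computed, and each inferred tree's
#' distance is the sum of absolute differences of the lower-triangular
#' entries against the ground truth's matrix. Patterns occurring at several
#' nodes of one tree are mapped to the highest-mass node.
#'
#' @param truth ground-truth tree (a \code{\link{cloneGraph}} or anything
#'   \code{\link{asCloneGraph}} accepts).
#' @param inferred list of inferred trees (same types).
#' @param weighted use branch-length-weighted path lengths instead of hop
#'   counts (requires edge weights; hop counts are the default).
#' @return Numeric vector, one distance per inferred tree.
#' @export
consensusSpDistance <- function(truth, inferred, weighted = FALSE) {
    co <- function(x) if (inherits(x, "cloneGraph")) x else asCloneGraph(x)
    truth <- co(truth)
    inferred <- lapply(inferred, co)
    maps <- lapply(c(list(truth), inferred), .patternNodes)
    shared <- Reduce(intersect, lapply(maps, names))
    if (length(shared) == 0L)
        stop("no marker pattern shared by the ground truth and all inferred trees")
    dm <- function(cg, map) {
        g <- .cloneIgraph(cg)
        D <- igraph::distances(g, v = map[shared], to = map[shared],
                               weights = if (weighted) NULL else NA)
        D
    }
    D0 <- dm(truth, maps[[1L]])
    lt <- lower.tri(D0)
    vapply(seq_along(inferred), function(i) {
        Di <- dm(inferred[[i]], maps[[i + 1L]])
        sum(abs(Di[lt] - D0[lt]))
    }, numeric(1))
}

#' Tree summary statistics
#'
#' Computes the topological summaries used to compare samples: maximum depth
#' over occupied clones, number of occupied clones, number of big clones
#' (weight strictly above 0.01), total branch length over instantiated
#' non-root nodes, and per-depth clone weight sums (level mass).
#'
#' @param tree a \code{\linkS4class{TssbTree}} (typically a culled MAP or
#'   trace snapshot tree carrying assignments).
#' @return List with \code{maxDepth}, \code{nClones}, \code{nBigClones},
#'   \code{totalBranchLength}, \code{levelMass} (named by depth, starting
#'   at 0).
#' @export
treeSummary <- function(tree) {
    stopifnot(is(tree, "TssbTree"))
    pi <- cloneWeights(tree)
    keys <- names(tree@nodes)
    depth <- vapply(tree@nodes, function(n) length(n$path), integer(1))
    occ <- vapply(tree@nodes, function(n) length(n$assigned) > 0L, logical(1))
    lv <- tapply(pi, depth, sum)
    list(maxDepth = if (any(occ)) max(depth[occ]) else 0L,
         nClones = sum(occ),
         nBigClones = sum(pi > 0.01),
         totalBranchLength = sum(vapply(tree@nodes, `[[`, numeric(1), "t")[
             keys != "0"]),
         levelMass = lv)
}

#' Symmetrised Kullback-Leibler divergence
#'
#' KL(p||q) + KL(q||p) between two level-mass (or any discrete)
#' distributions. The shorter vector is padded with zeros to a common
#' support, both are smoothed by a small epsilon and renormalised.
#'
#' @param p,q nonnegative numeric vectors.
#' @param eps smoothing constant.
#' @return Nonnegative scalar; 0 iff the normalised distributions agree.
#' @export
symmetrizedKl <- function(p, q, eps = 1e-10) {
    n <- max(length(p), length(q))
    pad <- function(x) { x <- c(x, rep(0, n - length(x))) + eps; x / sum(x) }
    p <- pad(p); q <- pad(q)
    sum(p * log(p / q)) + sum(q * log(q / p))
}
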