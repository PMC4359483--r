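## Distance-based baseline pipelines: Jaccard distances, silhouette-selected
## hierarchical / k-centroids clustering, methyltype estimation, and rooted
## Hamming minimum spanning trees over the estimated clone patterns.

#' Jaccard distances between marker rows
#'
#' Pairwise Jaccard (asymmetric binary) distances: the proportion of sites
#' where exactly one of the two rows is 1, among sites where at least one
#' is. Computed with \code{stats::dist(method = "binary")}; a pair of
#' all-zero rows, for which the union is empty, is assigned distance 0.
#'
#' @param x a \code{\linkS4class{MarkerMatrix}} without missing entries.
#' @return A \code{dist} object.
#' @export
jaccardDistances <- function(x) {
    stopifnot(is(x, "MarkerMatrix"))
    if (any(is.na(x@values)))
        stop("baselines require a complete matrix (no missing entries)")
    d <- stats::dist(x@values, method = "binary")
    d[!is.finite(d)] <- 0
    d
}

#' Silhouette-based cluster number selection
#'
#' Clusters a distance matrix at every cluster number from 2 to
#' \code{min(kMax, N-1)} (complete-linkage hierarchical agglomeration cut at
#' k, or partitioning around medoids) and returns the clustering whose mean
#' silhouette width is highest.
#'
#' @param d a \code{dist} object (e.g. from \code{\link{jaccardDistances}}).
#' @param method \code{"hierarchical"} or \code{"k_centroids"}.
#' @param kMax largest candidate cluster number (default 20).
#' @return List with \code{k}, \code{labels} (integer vector) and
#'   \code{scores} (mean silhouette per candidate k). If all pairwise
#'   distances are zero the data are degenerate: a single cluster is
#'   returned with a warning.
#' @export
silhouetteSelect <- function(d, method = c("hierarchical", "k_centroids"),
                             kMax = 20L) {
    method <- match.arg(method)
    N <- attr(d, "Size")
    if (N < 3L) stop("need at least 3 observations for model selection")
    if (all(d == 0)) {
        warning("all pairwise distances are zero; returning a single cluster")
        return(list(k = 1L, labels = rep(1L, N), scores = numeric(0)))
    }
    ks <- 2L:min(kMax, N - 1L)
    hc <- if (method == "hierarchical") stats::hclust(d, method = "complete")
    scores <- stats::setNames(numeric(length(ks)), ks)
    labs <- vector("list", length(ks))
    for (i in seq_along(ks)) {
        labs[[i]] <- if (method == "hierarchical")
            unname(stats::cutree(hc, k = ks[i]))
        else
            cluster::pam(d, k = ks[i], diss = TRUE, cluster.only = TRUE)
        sil <- cluster::silhouette(labs[[i]], d)
        scores[i] <- mean(sil[, "sil_width"])
    }
    best <- which.max(scores)
    list(k = ks[best], labels = as.integer(labs[[best]]), scores = scores)
}

#' Per-cluster marker patterns (methyltypes)
#'
#' Estimates the binary marker pattern of each cluster. For hierarchical
#' clustering each pattern is the site-wise mean of the cluster's rows
#' thresholded at 0.5 (strictly greater maps to 1, so exact ties map to 0);
#' for k-centroids the pattern is the cluster's medoid row (the member
#' minimising the total Jaccard distance to the other members).
#'
#' @param x a complete \code{\linkS4class{MarkerMatrix}}.
#' @param labels integer cluster labels (1..k, all clusters non-empty).
#' @param method \code{"hierarchical"} or \code{"k_centroids"}.
#' @return Binary matrix, one row per cluster.
#' @export
estimateMethyltypes <- function(x, labels,
                                method = c("hierarchical", "k_centroids")) {
    method <- match.arg(method)
    v <- x@values
    ks <- sort(unique(labels))
    if (!all(seq_len(max(labels)) %in% ks))
        stop("empty cluster in labels")
    out <- matrix(0, length(ks), ncol(v))
    for (k in ks) {
        rows <- v[labels == k, , drop = FALSE]
        out[k, ] <- if (method == "hierarchical") {
            as.numeric(colMeans(rows) > 0.5)
        } else if (nrow(rows) == 1L) {
            rows[1L, ]
        } else {
            dd <- as.matrix(stats::dist(rows, method = "binary"))
            dd[!is.finite(dd)] <- 0
            rows[which.min(rowSums(dd)), ]
        }
    }
    out
}

#' Rooted minimum spanning tree over clone patterns
#'
#' Builds the minimum spanning tree of the pairwise Hamming distances
#' between clone patterns (via \code{igraph}), roots it at the pattern with
#' the fewest 1s (ties broken towards the lexicographically smallest
#' pattern) and directs all edges away from the root.
#'
#' @param patterns binary matrix, one row per clone.
#' @return List with \code{edges} (two-column matrix of parent, child row
#'   indices; zero rows for a single clone) and \code{root} (row index).
#' @export
hammingMst <- function(patterns) {
    k <- nrow(patterns)
    if (k == 0L) stop("need at least one pattern")
    ones <- rowSums(patterns)
    lex <- apply(patterns, 1L, paste, collapse = "")
    root <- order(ones, lex)[1L]
    if (k == 1L)
        return(list(edges = matrix(integer(0), 0, 2), root = root))
    H <- as.matrix(stats::dist(patterns, method = "manhattan"))
    g <- igraph::graph_from_adjacency_matrix(H, mode = "undirected",
                                             weighted = TRUE)
    mt <- igraph::mst(g)
    el <- igraph::as_edgelist(mt, names = FALSE)
    ## direct edges away from the root by breadth-first traversal
    adj <- lapply(seq_len(k), function(i)
        c(el[el[, 1] == i, 2], el[el[, 2] == i, 1]))
    parent <- rep(NA_integer_, k)
    queue <- root
    seen <- rep(FALSE, k); seen[root] <- TRUE
    while (length(queue)) {
        u <- queue[1L]; queue <- queue[-1L]
        for (w in adj[[u]]) if (!seen[w]) {
            seen[w] <- TRUE
            parent[w] <- u
            queue <- c(queue, w)
        }
    }
    kids <- which(!is.na(parent))
    list(edges = cbind(parent = parent[kids], child = kids), root = root)
}

#' Run a complete baseline pipeline
#'
#' Jaccard distances, silhouette-selected clustering, methyltype estimation
#' and the rooted Hamming minimum spanning tree, bundled as the comparison
#' method of the benchmark.
#'
#' @param x a complete \code{\linkS4class{MarkerMatrix}}.
#' @param method \code{"hierarchical"} or \code{"k_centroids"}.
#' @param kMax largest candidate cluster number.
#' @return A \code{\linkS4class{BaselineFit}}.
#' @export
runBaseline <- function(x, method = c("hierarchical", "k_centroids"),
                        kMax = 20L) {
    method <- match.arg(method)
    d <- jaccardDistances(x)
    sel <- silhouetteSelect(d, method, kMax)
    mt <- estimateMethyltypes(x, sel$labels, method)
    tr <- hammingMst(mt)
    new("BaselineFit", method = method, labels = as.integer(sel$labels),
        methyltypes = mt, edges = tr$edges, root = tr$root)
}
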