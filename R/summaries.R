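## Posterior summaries of the MCMC trace: co-clustering, MPEAR partition
## selection, and MAP tree extraction by big-node-number grouping.

#' Posterior similarity matrix
#'
#' N x N matrix whose (a, b) entry is the fraction of retained MCMC samples
#' in which observations a and b are assigned to the same clone. Symmetric
#' with unit diagonal.
#'
#' @param trace a \code{\linkS4class{McmcTrace}}.
#' @return N x N numeric matrix.
#' @export
posteriorSimilarity <- function(trace) {
    stopifnot(is(trace, "McmcTrace"))
    snaps <- trace@snapshots
    if (!length(snaps)) stop("empty trace")
    N <- trace@nObs
    P <- matrix(0, N, N)
    for (s in snaps) {
        f <- match(s$assign, unique(s$assign))
        Z <- matrix(0, N, max(f))
        Z[cbind(seq_len(N), f)] <- 1
        P <- P + tcrossprod(Z)
    }
    P / length(snaps)
}

#' Posterior expected adjusted Rand index of a candidate partition
#'
#' Fritsch-Ickstadt PEAR: the expected adjusted Rand index between a
#' candidate partition and the posterior clustering, computed in closed form
#' from the posterior similarity matrix.
#'
#' @param labels candidate partition (any label type).
#' @param psm posterior similarity matrix.
#' @return The PEAR score (a scalar).
#' @export
pearIndex <- function(labels, psm) {
    N <- length(labels)
    stopifnot(nrow(psm) == N, ncol(psm) == N)
    lt <- lower.tri(psm)
    I <- outer(labels, labels, "==")[lt]
    p <- psm[lt]
    B <- length(p)
    sumIp <- sum(I * p); sumI <- sum(I); sump <- sum(p)
    expIp <- sumI * sump / B
    den <- 0.5 * (sumI + sump) - expIp
    if (den == 0) return(0)
    (sumIp - expIp) / den
}

#' Summary partition by PEAR maximisation
#'
#' Generates candidate partitions by cutting an average-linkage hierarchical
#' clustering of one minus the posterior similarity matrix at every cluster
#' number from 1 to \code{kMax}, and returns the candidate with the highest
#' posterior expected adjusted Rand index.
#'
#' @param psm posterior similarity matrix (symmetric, unit diagonal).
#' @param kMax largest candidate cluster number; default
#'   \code{min(N, 20)}.
#' @return Integer vector of summary cluster labels.
#' @export
mpearSummary <- function(psm, kMax = min(nrow(psm), 20L)) {
    N <- nrow(psm)
    if (N == 1L) return(1L)
    hc <- stats::hclust(stats::as.dist(1 - psm), method = "average")
    best <- rep(1L, N); bestScore <- -Inf
    for (k in seq_len(kMax)) {
        lab <- stats::cutree(hc, k = k)
        sc <- pearIndex(lab, psm)
        if (sc > bestScore) {
            bestScore <- sc
            best <- lab
        }
    }
    unname(best)
}

#' Empirical MAP tree from a trace
#'
#' Groups retained samples by their big-node number (count of clones with
#' weight above 0.01), takes the most frequent group (ties broken towards
#' fewer big nodes, i.e. parsimony) and returns, from that group, the
#' snapshot with the highest complete-data log-likelihood.
#'
#' @param trace a \code{\linkS4class{McmcTrace}}.
#' @return The selected snapshot, a list with elements \code{nodes},
#'   \code{assign}, \code{pi}, \code{logLik}, \code{bigNodes} (convert with
#'   \code{\link{snapshotToTree}}).
#' @export
selectMapTree <- function(trace) {
    stopifnot(is(trace, "McmcTrace"))
    snaps <- trace@snapshots
    if (!length(snaps)) stop("empty trace")
    big <- vapply(snaps, `[[`, numeric(1), "bigNodes")
    tab <- table(big)
    winner <- as.numeric(names(tab)[tab == max(tab)])
    winner <- min(winner)
    grp <- which(big == winner)
    ll <- vapply(snaps[grp], `[[`, numeric(1), "logLik")
    snaps[[grp[which.max(ll)]]]
}
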