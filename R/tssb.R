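## Tree-structured stick-breaking process (TSSB) core.
##
## Clone sizes are generated by interleaving two stick-breaking processes:
## at each node a depth-wise stick nu ~ Beta(1, lambda^depth * alpha0) keeps
## a fraction of the arriving mass, and the remainder is split among the
## node's children by breadth-wise sticks psi ~ Beta(1, gamma). The weight
## of the i-th child's subtree relative to the remainder is
## phi_i = psi_i * prod_{j<i} (1 - psi_j).

.newNode <- function(path, nu, psi = numeric(0), theta = numeric(0),
                     t = NA_real_, assigned = integer(0)) {
    list(path = as.integer(path), nu = nu, psi = psi, theta = theta,
         t = t, assigned = assigned)
}

## Beta draws clamped off {0,1}: the stick log-priors (Beta(1, b) with
## b < 1) are unbounded at 1, so exact boundary draws would break the
## Metropolis ratios downstream.
.rbetaSafe <- function(n, a, b) {
    pmin(pmax(stats::rbeta(n, a, b), 1e-12), 1 - 1e-12)
}

#' Relative weight of a child subtree
#'
#' Computes the stick-breaking share \eqn{\phi_i = \psi_i \prod_{j<i}
#' (1-\psi_j)} of the i-th child given the breadth-wise sticks of its elder
#' siblings.
#'
#' @param psi breadth-wise stick of the child itself, in [0,1].
#' @param eldersPsi numeric vector of the sticks of children 1..(i-1) of the
#'   same parent (empty for the first child).
#' @return The child's relative subtree weight, in [0,1].
#' @examples
#' branchWeight(0.7)                 # first child: 0.7
#' branchWeight(1.0, c(0.2, 0.3))    # third child: 1 * 0.8 * 0.7 = 0.56
#' @export
branchWeight <- function(psi, eldersPsi = numeric(0)) {
    p <- c(eldersPsi, psi)
    if (any(p < 0) || any(p > 1))
        stop("stick variables must lie in [0,1]")
    psi * prod(1 - eldersPsi)
}

## phi vector for all drawn sticks of one node
.phiVec <- function(psi) {
    if (!length(psi)) return(numeric(0))
    psi * cumprod(c(1, 1 - psi))[seq_along(psi)]
}

## Mass bookkeeping over an instantiated node list. Returns, per node key:
## pi (own weight), arriving (mass entering the subtree), residual (mass of
## the node's un-instantiated descendants, i.e. drawn-but-vacant sticks and
## the unbroken remainder of the psi stick).
.treeMass <- function(nodes) {
    allKeys <- names(nodes)
    depths <- vapply(nodes, function(n) length(n$path), integer(1))
    keys <- allKeys[order(depths)]           # parents before children
    pi <- arriving <- residual <- stats::setNames(numeric(length(keys)), keys)
    childIdx <- stats::setNames(rep(list(integer(0)), length(keys)), keys)
    for (k in keys) {
        p <- nodes[[k]]$path
        if (length(p)) {
            pk <- parentKey(k)
            childIdx[[pk]] <- c(childIdx[[pk]], p[length(p)])
        }
    }
    arriving["0"] <- 1
    for (k in keys) {
        nd <- nodes[[k]]
        a <- arriving[[k]]
        pi[[k]] <- nd$nu * a
        rest <- a * (1 - nd$nu)
        phi <- .phiVec(nd$psi)
        inst <- childIdx[[k]]
        for (i in inst)
            arriving[[paste(c(k, i), collapse = ".")]] <- rest * phi[i]
        residual[[k]] <- rest * (1 - sum(phi[inst]))
    }
    list(pi = pi, arriving = arriving, residual = residual)
}

#' Clone weights of an instantiated tree
#'
#' Computes the mixture weight \eqn{\pi_\epsilon} of every instantiated node:
#' \eqn{\pi_\emptyset = \nu_\emptyset} for the root and
#' \eqn{\pi_\epsilon = \nu_\epsilon \phi_\epsilon \prod_{\epsilon'}
#' \phi_{\epsilon'} (1-\nu_{\epsilon'})} over all ancestors \eqn{\epsilon'}
#' otherwise. The weights sum to at most one; the deficit is the mass of the
#' un-instantiated remainder of the infinite tree, returned as attribute
#' \code{"residual"}.
#'
#' @param tree a \code{\linkS4class{TssbTree}}.
#' @return Named numeric vector of clone weights, keyed by node key
#'   (root \code{"0"}); attribute \code{"residual"} holds the
#'   un-instantiated mass.
#' @export
cloneWeights <- function(tree) {
    stopifnot(is(tree, "TssbTree"))
    m <- .treeMass(tree@nodes)
    structure(m$pi, residual = sum(m$residual))
}

## Size-biased lazy instantiation: repeatedly instantiate the vacant stick
## receiving the most mass until the un-instantiated mass drops below `tol`
## (or caps are hit). New nodes draw nu from its depth Beta prior, a branch
## length from the branch-length prior, and theta from the parent-child
## transition kernel.
.expandNodes <- function(nodes, hypers, params, tol = 1e-3,
                         maxNodes = 500L, maxDepth = Inf) {
    m <- .treeMass(nodes)
    keys <- names(nodes)
    nu <- vapply(nodes[keys], `[[`, numeric(1), "nu")
    rest <- m$arriving[keys] * (1 - nu)      # mass passed below each node
    resid <- m$residual[keys]                # of which: not yet instantiated
    depth <- stats::setNames(keyDepth(keys), keys)
    inst <- stats::setNames(rep(list(integer(0)), length(keys)), keys)
    for (k in keys) {
        p <- nodes[[k]]$path
        if (length(p)) {
            pk <- parentKey(k)
            inst[[pk]] <- c(inst[[pk]], p[length(p)])
        }
    }
    repeat {
        open <- depth < maxDepth & resid > 0
        if (!any(open) || sum(resid[open]) <= tol ||
            length(nodes) >= maxNodes)
            break
        k <- names(which.max(resid[open]))
        nd <- nodes[[k]]
        vacant <- setdiff(seq_along(nd$psi), inst[[k]])
        if (length(vacant)) {
            i <- vacant[1L]
            phi <- .phiVec(nd$psi)[i]
        } else {
            psiNew <- .rbetaSafe(1, 1, hypers$gamma)
            phi <- psiNew * prod(1 - nd$psi)
            nd$psi <- c(nd$psi, psiNew)
            i <- length(nd$psi)
            nodes[[k]] <- nd
        }
        childPath <- c(nd$path, i)
        ck <- labelKey(childPath)
        d <- length(childPath)
        t <- stats::rexp(1)
        child <- .newNode(
            path = childPath,
            nu = .rbetaSafe(1, 1, hypers$lambda^d * hypers$alpha0),
            theta = .drawChildTheta(nd$theta, t, params),
            t = t)
        nodes[[ck]] <- child
        inst[[k]] <- c(inst[[k]], i)
        arrivingChild <- rest[[k]] * phi
        resid[[k]] <- max(resid[[k]] - arrivingChild, 0)
        rest[ck] <- arrivingChild * (1 - child$nu)
        resid[ck] <- rest[[ck]]
        depth[ck] <- d
        inst[[ck]] <- integer(0)
    }
    nodes
}

#' Instantiate a tree towards stick depletion
#'
#' Extends the instantiated portion of the tree by size-biased instantiation
#' of vacant sticks (new nodes draw their stick variables, branch lengths and
#' parameters from the prior) until the un-instantiated mass is below
#' \code{tol} or a node/depth cap is reached.
#'
#' @param tree a \code{\linkS4class{TssbTree}}.
#' @param params an \code{\link{evolutionParams}} object used to draw the
#'   parameters of newly instantiated nodes.
#' @param tol target bound on the un-instantiated mass.
#' @param maxNodes,maxDepth caps on the instantiated tree.
#' @return The extended \code{TssbTree}.
#' @export
expandTree <- function(tree, params, tol = 1e-3, maxNodes = 500L,
                       maxDepth = Inf) {
    tree@nodes <- .expandNodes(tree@nodes, tree@hypers, params, tol,
                               maxNodes, maxDepth)
    tree
}

#' Sample a finite tree and assignments from the TSSB prior
#'
#' Draws clone weights \eqn{\pi \sim TSSB(\lambda, \alpha_0, \gamma)} and
#' assignments \eqn{\epsilon_n \mid \pi \sim Discrete(\pi)} by lazy
#' inverse-CDF descent: nodes (and their stick variables, branch lengths and
#' parameters) are instantiated on demand as observations descend into them.
#'
#' @param hypers list with \code{lambda}, \code{alpha0}, \code{gamma}
#'   (all positive).
#' @param nObs number of assignments to draw.
#' @param M number of marker sites (length of the per-node parameter vector).
#' @param params an \code{\link{evolutionParams}} for drawing node
#'   parameters; defaults to the methylation model at equilibrium 1/2.
#' @param maxDepth descent cap. With a depth-decay base above one the depth
#'   sticks shrink geometrically, so a small fraction of draws would
#'   otherwise descend without bound; a draw reaching the cap is assigned
#'   to the node at the cap.
#' @return A list with components \code{tree} (a
#'   \code{\linkS4class{TssbTree}}) and \code{assignments} (character vector
#'   of node keys, length \code{nObs}).
#' @examples
#' set.seed(1)
#' pr <- samplePriorTree(list(lambda = 2, alpha0 = 0.3, gamma = 0.1), nObs = 5)
#' cloneWeights(pr$tree)
#' @export
samplePriorTree <- function(hypers, nObs, M = 8L,
                            params = evolutionParams("methylation", 0.5),
                            maxDepth = 50L) {
    if (hypers$lambda <= 0 || hypers$alpha0 <= 0 || hypers$gamma <= 0)
        stop("TSSB hyperparameters must be positive")
    if (nObs < 1) stop("nObs must be at least 1")
    nodes <- list("0" = .newNode(
        integer(0), nu = .rbetaSafe(1, 1, hypers$alpha0),
        theta = rlaplace(M, -params$mu, params$Lambda)))
    assign <- character(nObs)
    for (n in seq_len(nObs)) {
        u <- stats::runif(1)
        key <- "0"
        repeat {
            nd <- nodes[[key]]
            if (u < nd$nu || length(nd$path) >= maxDepth) break
            u <- (u - nd$nu) / (1 - nd$nu)
            i <- 1L
            repeat {
                if (i > length(nd$psi)) {
                    nd$psi <- c(nd$psi, .rbetaSafe(1, 1, hypers$gamma))
                    nodes[[key]] <- nd
                }
                if (u < nd$psi[i]) {
                    u <- u / nd$psi[i]
                    break
                }
                u <- (u - nd$psi[i]) / (1 - nd$psi[i])
                i <- i + 1L
            }
            childKey <- paste(c(key, i), collapse = ".")
            if (is.null(nodes[[childKey]])) {
                d <- length(nd$path) + 1L
                t <- stats::rexp(1)
                nodes[[childKey]] <- .newNode(
                    c(nd$path, i),
                    nu = .rbetaSafe(1, 1, hypers$lambda^d * hypers$alpha0),
                    theta = .drawChildTheta(nd$theta, t, params), t = t)
            }
            key <- childKey
        }
        assign[n] <- key
    }
    for (key in unique(assign))
        nodes[[key]]$assigned <- which(assign == key)
    list(tree = new("TssbTree", nodes = nodes, hypers = hypers),
         assignments = assign)
}

#' Remove empty leaf-side nodes
#'
#' Drops instantiated nodes that carry no assigned observations and have no
#' occupied descendant, keeping the node map prefix-closed. Stick variables
#' of surviving nodes are untouched, so the weights of surviving clones are
#' unchanged (vacated sticks re-join the un-instantiated residual mass).
#'
#' @param tree a \code{\linkS4class{TssbTree}}.
#' @return The culled \code{TssbTree}; idempotent.
#' @export
cullEmpty <- function(tree) {
    tree@nodes <- .cullNodes(tree@nodes)
    tree
}

.cullNodes <- function(nodes) {
    depths <- vapply(nodes, function(n) length(n$path), integer(1))
    keys <- names(nodes)[order(depths)]
    keep <- stats::setNames(vapply(nodes[keys],
        function(n) length(n$assigned) > 0L, logical(1)), keys)
    for (k in rev(keys)) {
        if (keep[[k]] && length(nodes[[k]]$path))
            keep[[parentKey(k)]] <- TRUE
    }
    keep[["0"]] <- TRUE
    nodes <- nodes[keys[keep[keys]]]
    ## trim trailing psi sticks beyond the last surviving child
    for (k in names(nodes)) {
        kids <- integer(0)
        for (kk in names(nodes)) {
            p <- nodes[[kk]]$path
            if (length(p) && identical(parentKey(kk), k))
                kids <- c(kids, p[length(p)])
        }
        last <- if (length(kids)) max(kids) else 0L
        if (length(nodes[[k]]$psi) > last)
            nodes[[k]]$psi <- nodes[[k]]$psi[seq_len(last)]
    }
    nodes
}
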