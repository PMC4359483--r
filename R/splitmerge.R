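## Split-merge Metropolis-Hastings move.
##
## Per-observation Gibbs updates cross between "one mixed clone" and "two
## separated clones" configurations only through a bottleneck of
## tiny-probability intermediate states: a fresh candidate node must
## capture observations one at a time while its stick mass is still
## negligible, and a node whose subtree has emptied has its depth stick
## driven towards one, strangling later births. The split-merge move
## proposes the whole transition in one step with an exact
## Metropolis-Hastings ratio, so the chain can hop between merged and
## split modes directly.
##
## SPLIT: choose an occupied node, a marker site and a direction; all of
## the node's observations carrying that state at that site (missing
## entries stay put) move into a brand-new last child. The child's branch
## length comes from the branch-length prior, its parameters from
## site-wise Laplace proposals centred on the moved group's empirical
## logit frequencies, and the child depth stick plus the parent's depth
## stick and full breadth-stick vector are re-drawn from their Beta full
## conditionals under the proposed allocation (so elder siblings make
## stick room for the new child). The partition is deterministic given
## (node, site, direction), so the reverse MERGE -- folding a childless,
## last-stick child whose observations are exactly such a site split of
## the combined group back into its parent, re-drawing the parent's
## sticks under the merged allocation -- has a computable proposal
## density, including the multiplicity of (site, direction) choices that
## induce the same partition. All proposal factors are explicit, making
## the acceptance ratio exact; the target distribution is unchanged.

.SM_THETA_SCALE <- 0.35

## eligible split sources: occupied nodes with >= 2 observations whose
## child would not exceed maxDepth
.splitSources <- function(state) {
    maxDepth <- state$config$maxDepth
    keys <- names(state$nodes)
    keys[vapply(keys, function(k) {
        nd <- state$nodes[[k]]
        length(nd$path) + 1L <= maxDepth && length(nd$assigned) >= 2L
    }, logical(1))]
}

## the (site, direction) split of an observation set: indices moved to the
## child, or NULL if the split is degenerate (empty side)
.sitePartition <- function(state, obs, site, dir) {
    pats <- state$cache$pat[obs]
    v <- state$cache$Xz[pats, site]
    v[state$cache$Mz[pats, site] == 0] <- NA
    move <- obs[!is.na(v) & v == dir]
    if (length(move) == 0L || length(move) == length(obs)) return(NULL)
    move
}

## how many (site, direction) choices induce this exact partition
.partitionMultiplicity <- function(state, obs, moved) {
    memb <- obs %in% moved
    if (!any(memb) || all(memb)) return(0L)
    pats <- state$cache$pat[obs]
    V <- state$cache$Xz[pats, , drop = FALSE]
    OK <- state$cache$Mz[pats, , drop = FALSE] == 1
    n <- length(obs)
    hits <- 0L
    for (dir in c(0, 1)) {
        sel <- (V == dir) & OK
        hits <- hits + sum(colSums(sel == memb) == n)
    }
    hits
}

## deterministic child theta proposal locations: empirical logit
## frequencies of the moved group, clamped
.childThetaLoc <- function(state, moved) {
    cnt <- tabulate(state$cache$pat[moved], state$cache$U)
    ones <- as.numeric(crossprod(state$cache$Xz, cnt))
    tot <- as.numeric(crossprod(state$cache$Mz, cnt))
    f <- ifelse(tot > 0, ones / pmax(tot, 1), 0.5)
    stats::qlogis(pmin(pmax(f, 0.02), 0.98))
}

## Beta full-conditional parameters of a node's depth stick and breadth
## sticks under the given allocation
.stickParams <- function(nodes, key, hypers) {
    cnts <- .subtreeCounts(nodes)
    nd <- nodes[[key]]
    d <- length(nd$path)
    keys <- names(cnts$n)
    out <- list(nuA = 1 + cnts$n[[key]],
                nuB = hypers$lambda^d * hypers$alpha0 +
                      cnts$s[[key]] - cnts$n[[key]])
    if (length(nd$psi)) {
        m <- vapply(seq_along(nd$psi), function(i) {
            ck <- paste(c(key, i), collapse = ".")
            if (ck %in% keys) cnts$s[[ck]] else 0
        }, numeric(1))
        later <- rev(cumsum(rev(m))) - m
        out$psiA <- 1 + m
        out$psiB <- hypers$gamma + later
    } else {
        out$psiA <- out$psiB <- numeric(0)
    }
    out
}

## log density of proposing exactly these parent/child stick and parameter
## values under the given allocation (nodes must reflect the allocation);
## both the child's and the parent's theta are proposed around the
## empirical logit frequencies of their respective observation groups, so
## a split refits both halves at once
.splitProposalLogDens <- function(nodes, hypers, parentKey, parent, child,
                                  childLoc, parentLoc) {
    pp <- .stickParams(nodes, parentKey, hypers)
    cp <- .stickParams(nodes, labelKey(child$path), hypers)
    stats::dexp(child$t, 1, log = TRUE) +
        sum(dlaplaceLog(child$theta, childLoc, .SM_THETA_SCALE)) +
        sum(dlaplaceLog(parent$theta, parentLoc, .SM_THETA_SCALE)) +
        stats::dbeta(child$nu, cp$nuA, cp$nuB, log = TRUE) +
        stats::dbeta(parent$nu, pp$nuA, pp$nuB, log = TRUE) +
        sum(stats::dbeta(parent$psi, pp$psiA, pp$psiB, log = TRUE))
}

## log density of the merge proposal's redraw (parent sticks and theta
## under the merged allocation; nodes must reflect it)
.mergeProposalLogDens <- function(nodes, hypers, parentKey, parent,
                                  parentLoc) {
    pp <- .stickParams(nodes, parentKey, hypers)
    sum(dlaplaceLog(parent$theta, parentLoc, .SM_THETA_SCALE)) +
        stats::dbeta(parent$nu, pp$nuA, pp$nuB, log = TRUE) +
        sum(stats::dbeta(parent$psi, pp$psiA, pp$psiB, log = TRUE))
}

## eligible merge targets: non-root, occupied, childless, last stick of
## the parent, and the combined group admits at least one
## (site, direction) split reproducing exactly the child's observations
.mergeTargets <- function(state) {
    keys <- names(state$nodes)
    hasKids <- stats::setNames(rep(FALSE, length(keys)), keys)
    for (k in keys) if (k != "0") hasKids[[parentKey(k)]] <- TRUE
    keys[vapply(keys, function(k) {
        if (k == "0" || hasKids[[k]]) return(FALSE)
        nd <- state$nodes[[k]]
        if (!length(nd$assigned)) return(FALSE)
        par <- state$nodes[[parentKey(k)]]
        if (!length(par$assigned)) return(FALSE)
        if (nd$path[length(nd$path)] != length(par$psi)) return(FALSE)
        .partitionMultiplicity(state, c(par$assigned, nd$assigned),
                               nd$assigned) > 0L
    }, logical(1))]
}

#' Split-merge move over clone assignments
#'
#' Proposes either splitting an occupied node's observations on a marker
#' site (all observations carrying the chosen state at the chosen site
#' move into a new child clone, with the affected sticks re-drawn from
#' their full conditionals), or merging a childless single-split child
#' back into its parent, and accepts with an exact Metropolis-Hastings
#' ratio on the full joint density. This collective move lets the sampler
#' cross between merged and separated clone configurations that
#' per-observation updates reach only through vanishing-probability
#' intermediate states.
#'
#' @param state a \code{"McmcState"}.
#' @return The updated state.
#' @export
splitMergeMove <- function(state) {
    state$A <- rateMatrix(state$params$kind, state$params$betaM)
    if (is.null(state$jcache)) state$jcache <- .logJoint(state)
    if (stats::runif(1) < 0.5) .trySplit(state) else .tryMerge(state)
}

.pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

.trySplit <- function(state) {
    src <- .splitSources(state)
    if (!length(src)) return(state)
    k <- .pick1(src)
    nd <- state$nodes[[k]]
    site <- .pick1(seq_len(state$cache$M))
    dir <- .pick1(c(0, 1))
    moved <- .sitePartition(state, nd$assigned, site, dir)
    if (is.null(moved)) return(state)
    h <- state$hypers

    ## build the candidate allocation first, then draw sticks from their
    ## conditionals under it
    i <- length(nd$psi) + 1L
    childPath <- c(nd$path, i)
    ck <- labelKey(childPath)
    remaining <- setdiff(nd$assigned, moved)
    childLoc <- .childThetaLoc(state, moved)
    parentLoc <- .childThetaLoc(state, remaining)
    mergedLoc <- .childThetaLoc(state, nd$assigned)
    child <- .newNode(childPath, nu = 0.5,
                      theta = rlaplace(state$cache$M, childLoc,
                                       .SM_THETA_SCALE),
                      t = stats::rexp(1), assigned = moved)
    cand <- state
    cand$nodes[[k]]$psi <- c(nd$psi, 0.5)
    cand$nodes[[k]]$assigned <- remaining
    cand$nodes[[k]]$theta <- rlaplace(state$cache$M, parentLoc,
                                      .SM_THETA_SCALE)
    cand$nodes[[ck]] <- child
    cand$assign[moved] <- ck

    pp <- .stickParams(cand$nodes, k, h)
    cp <- .stickParams(cand$nodes, ck, h)
    cand$nodes[[ck]]$nu <- .rbetaSafe(1, cp$nuA, cp$nuB)
    cand$nodes[[k]]$nu <- .rbetaSafe(1, pp$nuA, pp$nuB)
    cand$nodes[[k]]$psi <- .rbetaSafe(length(pp$psiA), pp$psiA, pp$psiB)

    logFwd <- -log(length(src)) +
        log(.partitionMultiplicity(state, nd$assigned, moved)) -
        log(2 * state$cache$M) +
        .splitProposalLogDens(cand$nodes, h, k, cand$nodes[[k]],
                              cand$nodes[[ck]], childLoc, parentLoc)
    mergeTargets <- .mergeTargets(cand)
    ## reverse merge re-draws the parent's sticks and theta under the
    ## merged allocation and must land on the current values
    logRev <- -log(length(mergeTargets)) +
        .mergeProposalLogDens(state$nodes, h, k, state$nodes[[k]],
                              mergedLoc)
    j1 <- .logJoint(cand)
    logA <- j1 - state$jcache + logRev - logFwd
    if (is.finite(logA) && log(stats::runif(1)) < logA) {
        cand$jcache <- j1
        cand
    } else state
}

.tryMerge <- function(state) {
    tgt <- .mergeTargets(state)
    if (!length(tgt)) return(state)
    ck <- .pick1(tgt)
    nd <- state$nodes[[ck]]
    pk <- parentKey(ck)
    obs <- nd$assigned
    h <- state$hypers

    parentObs <- state$nodes[[pk]]$assigned
    cand <- state
    cand$nodes[[pk]]$assigned <- c(parentObs, obs)
    cand$nodes[[pk]]$psi <-
        cand$nodes[[pk]]$psi[-length(cand$nodes[[pk]]$psi)]
    cand$nodes[[ck]] <- NULL
    cand$assign[obs] <- pk
    mergedLoc <- .childThetaLoc(state, c(parentObs, obs))
    cand$nodes[[pk]]$theta <- rlaplace(state$cache$M, mergedLoc,
                                       .SM_THETA_SCALE)
    pp <- .stickParams(cand$nodes, pk, h)
    cand$nodes[[pk]]$nu <- .rbetaSafe(1, pp$nuA, pp$nuB)
    if (length(pp$psiA))
        cand$nodes[[pk]]$psi <- .rbetaSafe(length(pp$psiA), pp$psiA,
                                           pp$psiB)

    src <- .splitSources(cand)
    if (!pk %in% src) return(state)
    childLoc <- .childThetaLoc(state, obs)
    parentLoc <- .childThetaLoc(state, parentObs)
    logRev <- -log(length(src)) +
        log(.partitionMultiplicity(cand, cand$nodes[[pk]]$assigned, obs)) -
        log(2 * cand$cache$M) +
        .splitProposalLogDens(state$nodes, h, pk, state$nodes[[pk]],
                              state$nodes[[ck]], childLoc, parentLoc)
    logFwd <- -log(length(tgt)) +
        .mergeProposalLogDens(cand$nodes, h, pk, cand$nodes[[pk]],
                              mergedLoc)
    j1 <- .logJoint(cand)
    logA <- j1 - state$jcache + logRev - logFwd
    if (is.finite(logA) && log(stats::runif(1)) < logA) {
        cand$jcache <- j1
        cand
    } else state
}
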