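## MCMC over the joint posterior of assignments, tree structure, clone
## parameters, branch lengths and kernel hyperparameters.
##
## One sweep comprises: (a) assignment resampling over the instantiated tree
## after size-biased instantiation of candidate nodes, (b) per-node,
## per-site Metropolis updates of theta, (c) Metropolis updates of branch
## lengths, (d) conjugate Beta resampling of the nu/psi sticks given subtree
## counts, (e) Metropolis updates of the kernel hyperparameters mu and
## Lambda, (f) culling of empty nodes. A swap-clone Metropolis move
## exchanges the parameters, assigned data and mass of two random nodes;
## states with an empty root are invalid and are repaired by further swaps
## involving the root.

#' MCMC configuration
#'
#' Defaults reproduce the full sampling schedule (burn-in 30,000 sweeps,
#' 50,000 further sweeps thinned by 5, so 10,000 retained samples) and the
#' fixed tree hyperparameters \eqn{\lambda = 2}, \eqn{\alpha_0 = 0.3},
#' \eqn{\gamma = 0.1}.
#'
#' @param burnin number of discarded initial sweeps.
#' @param nKeep number of post-burn-in sweeps.
#' @param thin retain every \code{thin}-th post-burn-in sweep.
#' @param seed RNG seed used by \code{\link{runMcmc}}.
#' @param lambda,alpha0,gamma TSSB hyperparameters.
#' @param eta state-call threshold of the evolution model.
#' @param muInit,LambdaInit initial values of the Laplace kernel mode
#'   location and scale.
#' @param updateHypers resample \code{mu} and \code{Lambda}? (Disable to fix
#'   the kernel, e.g. for targeted diagnostics.)
#' @param thetaStep standard deviation of the per-site Gaussian component of
#'   the theta proposal.
#' @param signFlipProb probability of proposing around the reflected value
#'   \code{-theta} instead of \code{theta} (the proposal mixture is
#'   symmetric, so plain Metropolis acceptance applies; the reflected
#'   component lets sites cross between the two Laplace modes).
#' @param tStep,muStep,LambdaStep random-walk scales for branch lengths
#'   (log scale), \code{mu} and \code{Lambda} (log scale).
#' @param massTol un-instantiated stick mass tolerated when enumerating
#'   candidate nodes for assignment resampling.
#' @param candidateNodes per-sweep budget of freshly instantiated candidate
#'   nodes offered to the assignment step (candidates that attract no
#'   observations are culled again within the sweep).
#' @param assignScans number of assignment-and-stick resampling scans per
#'   sweep. New clones are born when a freshly instantiated candidate
#'   captures observations and its sticks are immediately resampled from
#'   their full conditionals; several scans per sweep give the birth process
#'   several chances per sweep and markedly improve mixing over cluster
#'   splits at no change to the target distribution.
#' @param maxNodes,maxDepth caps on the instantiated tree.
#' @param nSwaps swap-clone moves attempted per sweep.
#' @param nSplitMerge split-merge moves attempted per sweep (see
#'   \code{\link{splitMergeMove}}).
#' @return A list with class \code{"mcmcConfig"}.
#' @examples
#' cfg <- mcmcConfig()
#' cfg$nKeep / cfg$thin   # 10000 retained samples
#' @export
mcmcConfig <- function(burnin = 30000L, nKeep = 50000L, thin = 5L,
                       seed = 1L, lambda = 2, alpha0 = 0.3, gamma = 0.1,
                       eta = 1, muInit = 4, LambdaInit = 1,
                       updateHypers = TRUE, thetaStep = 0.5,
                       signFlipProb = 0.3, tStep = 0.5, muStep = 0.25,
                       LambdaStep = 0.3, massTol = 1e-3,
                       candidateNodes = 40L, assignScans = 3L,
                       maxNodes = 300L, maxDepth = Inf, nSwaps = 1L,
                       nSplitMerge = 5L) {
    stopifnot(burnin >= 0, nKeep >= 1, thin >= 1, lambda > 0, alpha0 > 0,
              gamma > 0, thetaStep > 0, massTol > 0, maxNodes >= 1,
              candidateNodes >= 1)
    structure(list(burnin = as.integer(burnin), nKeep = as.integer(nKeep),
                   thin = as.integer(thin), seed = as.integer(seed),
                   lambda = lambda, alpha0 = alpha0, gamma = gamma,
                   eta = eta, muInit = muInit, LambdaInit = LambdaInit,
                   updateHypers = updateHypers, thetaStep = thetaStep,
                   signFlipProb = signFlipProb, tStep = tStep,
                   muStep = muStep, LambdaStep = LambdaStep,
                   massTol = massTol,
                   candidateNodes = as.integer(candidateNodes),
                   assignScans = as.integer(assignScans),
                   maxNodes = as.integer(maxNodes),
                   maxDepth = maxDepth, nSwaps = as.integer(nSwaps),
                   nSplitMerge = as.integer(nSplitMerge)),
              class = "mcmcConfig")
}

#' Equilibrium state frequencies from the data
#'
#' Estimates the equilibrium methylated/mutated frequency directly from the
#' population as the average of the non-missing entries, and the
#' unmethylated frequency as its complement.
#'
#' @param x a \code{\linkS4class{MarkerMatrix}}.
#' @return Named numeric vector \code{c(betaU, betaM)}.
#' @examples
#' estimateEquilibrium(MarkerMatrix(matrix(c(1, 0, 1, 0), 2)))
#' @export
estimateEquilibrium <- function(x) {
    stopifnot(is(x, "MarkerMatrix"))
    v <- x@values
    if (all(is.na(v))) stop("all entries are missing")
    bm <- mean(v, na.rm = TRUE)
    if (bm <= 0 || bm >= 1)
        stop("degenerate data: all non-missing entries identical")
    c(betaU = 1 - bm, betaM = bm)
}

## ---- state construction ----

#' Initialise an MCMC state
#'
#' Builds the sampler state: a root-only tree with the root parameter set
#' from the site-wise marker frequencies, all observations assigned to the
#' root, and cached sufficient statistics of the (pattern-collapsed) data.
#'
#' @param x a \code{\linkS4class{MarkerMatrix}}.
#' @param config an \code{\link{mcmcConfig}}.
#' @return A list with class \code{"McmcState"}.
#' @export
initMcmcState <- function(x, config = mcmcConfig()) {
    stopifnot(is(x, "MarkerMatrix"))
    v <- x@values
    N <- nrow(v); M <- ncol(v)
    beta <- estimateEquilibrium(x)
    params <- evolutionParams(x@kind, beta[["betaM"]],
                              mu = config$muInit, Lambda = config$LambdaInit,
                              eta = config$eta)
    ## collapse identical rows (incl. missingness pattern): observations with
    ## the same row are exchangeable, so assignments can be resampled as
    ## exact multinomial counts per pattern
    sig <- apply(v, 1L, function(r) paste(ifelse(is.na(r), "N", r),
                                          collapse = ""))
    pat <- match(sig, unique(sig))
    U <- max(pat)
    first <- match(seq_len(U), pat)
    Xu <- v[first, , drop = FALSE]
    Xz <- ifelse(is.na(Xu), 0, Xu)
    Mz <- 1 - is.na(Xu)
    cache <- list(N = N, M = M, U = U, pat = pat,
                  obsOfPat = split(seq_len(N), pat),
                  counts = as.integer(tabulate(pat, U)),
                  Xz = Xz, Mz = Mz)
    theta0 <- stats::qlogis(pmin(pmax(colMeans(v, na.rm = TRUE), 0.05), 0.95))
    nodes <- list("0" = .newNode(integer(0), nu = 0.5, theta = theta0,
                                 assigned = seq_len(N)))
    structure(list(nodes = nodes,
                   hypers = list(lambda = config$lambda,
                                 alpha0 = config$alpha0,
                                 gamma = config$gamma),
                   params = params, assign = rep("0", N), cache = cache,
                   kind = x@kind, config = config),
              class = "McmcState")
}

## K x U matrix of per-pattern log-likelihoods for all nodes
.logLikMatrix <- function(nodes, cache) {
    keys <- names(nodes)
    Th <- do.call(rbind, lapply(nodes, `[[`, "theta"))
    S <- pmin(pmax(stats::plogis(Th), .SIG_EPS), 1 - .SIG_EPS)
    L <- log(S) %*% t(cache$Xz) + log1p(-S) %*% t(cache$Mz - cache$Xz)
    rownames(L) <- keys
    L
}

## per-node site-wise counts of ones (c1) and non-missing (ct)
.nodeSiteStats <- function(state, key) {
    obs <- state$nodes[[key]]$assigned
    if (!length(obs))
        return(list(c1 = numeric(state$cache$M), ct = numeric(state$cache$M)))
    cnt <- tabulate(state$cache$pat[obs], state$cache$U)
    list(c1 = as.numeric(crossprod(state$cache$Xz, cnt)),
         ct = as.numeric(crossprod(state$cache$Mz, cnt)))
}

.childrenMap <- function(keys) {
    out <- stats::setNames(vector("list", length(keys)), keys)
    for (k in keys) {
        if (k == "0") next
        pk <- parentKey(k)
        out[[pk]] <- c(out[[pk]], k)
    }
    out
}

## n (own) and s (subtree) observation counts per node
.subtreeCounts <- function(nodes) {
    depths <- vapply(nodes, function(n) length(n$path), integer(1))
    keys <- names(nodes)[order(depths)]
    n <- vapply(nodes[keys], function(x) length(x$assigned), integer(1))
    s <- n
    for (k in rev(keys)) {
        if (k == "0") next
        pk <- parentKey(k)
        s[pk] <- s[pk] + s[k]
    }
    list(n = n, s = s)
}

## ---- sweep steps ----

.stepAssign <- function(state, cull = TRUE) {
    cfg <- state$config
    state$nodes <- .expandNodes(
        state$nodes, state$hypers, state$params, tol = cfg$massTol,
        maxNodes = min(cfg$maxNodes,
                       length(state$nodes) + cfg$candidateNodes),
        maxDepth = cfg$maxDepth)
    keys <- names(state$nodes)
    pi <- .treeMass(state$nodes)$pi[keys]
    L <- .logLikMatrix(state$nodes, state$cache)
    W <- log(pi) + L                      # K x U
    W <- exp(sweep(W, 2L, apply(W, 2L, max)))
    W <- sweep(W, 2L, colSums(W), "/")
    assign <- state$assign
    rootIdx <- match("0", keys)
    ## states with an empty root are invalid: rejection within the Gibbs
    ## step samples the assignment full conditional truncated to
    ## root-occupied configurations
    for (try in 1:50) {
        for (k in keys) state$nodes[[k]]$assigned <- integer(0)
        for (p in seq_len(state$cache$U)) {
            obs <- state$cache$obsOfPat[[p]]
            cnt <- stats::rmultinom(1L, length(obs), W[, p])[, 1L]
            if (length(obs) > 1L) obs <- sample(obs)
            pos <- 0L
            for (ki in which(cnt > 0L)) {
                sel <- obs[(pos + 1L):(pos + cnt[ki])]
                pos <- pos + cnt[ki]
                assign[sel] <- keys[ki]
                state$nodes[[keys[ki]]]$assigned <-
                    c(state$nodes[[keys[ki]]]$assigned, sel)
            }
        }
        if (length(state$nodes[["0"]]$assigned)) break
        if (try == 50L) {
            ## degenerate corner (root weight vanishing): project the
            ## observation with the highest root membership into the root
            best <- which.max(W[rootIdx, state$cache$pat])
            from <- assign[best]
            state$nodes[[from]]$assigned <-
                setdiff(state$nodes[[from]]$assigned, best)
            state$nodes[["0"]]$assigned <- best
            assign[best] <- "0"
        }
    }
    state$assign <- assign
    ## candidates that attracted no observations are dropped right away so
    ## the parameter updates only visit live nodes (kept alive between the
    ## scans of one sweep to avoid re-instantiating them)
    if (cull) state$nodes <- .cullNodes(state$nodes)
    state
}

## per-site log target for one node's theta vector
.thetaTarget <- function(theta, key, state, children, stats) {
    p <- state$params
    nd <- state$nodes[[key]]
    s <- pmin(pmax(stats::plogis(theta), .SIG_EPS), 1 - .SIG_EPS)
    tgt <- stats$c1 * log(s) + (stats$ct - stats$c1) * log1p(-s)
    if (key == "0") {
        tgt <- tgt + dlaplaceLog(theta, -p$mu, p$Lambda)
    } else {
        pr <- .transProbs(p, nd$t)
        thPa <- state$nodes[[parentKey(key)]]$theta
        wIn <- pr[1L] + (thPa >= p$eta) * (pr[2L] - pr[1L])
        tgt <- tgt + .mixLaplaceLog(theta, wIn, p$mu, p$Lambda)
    }
    for (ck in children) {
        ch <- state$nodes[[ck]]
        pr <- .transProbs(p, ch$t)
        w <- pr[1L] + (theta >= p$eta) * (pr[2L] - pr[1L])
        tgt <- tgt + .mixLaplaceLog(ch$theta, w, p$mu, p$Lambda)
    }
    tgt
}

.stepTheta <- function(state) {
    cfg <- state$config
    keys <- names(state$nodes)
    kids <- .childrenMap(keys)
    for (k in keys) {
        st <- .nodeSiteStats(state, k)
        cur <- state$nodes[[k]]$theta
        M <- length(cur)
        centre <- ifelse(stats::runif(M) < cfg$signFlipProb, -cur, cur)
        prop <- centre + stats::rnorm(M, 0, cfg$thetaStep)
        d <- .thetaTarget(prop, k, state, kids[[k]], st) -
             .thetaTarget(cur, k, state, kids[[k]], st)
        acc <- log(stats::runif(M)) < d
        cur[acc] <- prop[acc]
        state$nodes[[k]]$theta <- cur
    }
    state
}

.branchTarget <- function(state, key, t) {
    nd <- state$nodes[[key]]
    transitionLogPdf(nd$theta, state$nodes[[parentKey(key)]]$theta, t,
                     state$params) + stats::dexp(t, 1, log = TRUE)
}

.stepBranch <- function(state) {
    cfg <- state$config
    for (k in names(state$nodes)) {
        if (k == "0") next
        t0 <- state$nodes[[k]]$t
        t1 <- t0 * exp(stats::rnorm(1, 0, cfg$tStep))
        d <- .branchTarget(state, k, t1) - .branchTarget(state, k, t0) +
             log(t1) - log(t0)
        if (log(stats::runif(1)) < d) state$nodes[[k]]$t <- t1
    }
    state
}

.stepSticks <- function(state) {
    h <- state$hypers
    cnts <- .subtreeCounts(state$nodes)
    keys <- names(cnts$n)
    for (k in keys) {
        nd <- state$nodes[[k]]
        d <- length(nd$path)
        below <- cnts$s[[k]] - cnts$n[[k]]
        state$nodes[[k]]$nu <- .rbetaSafe(1, 1 + cnts$n[[k]],
                                            h$lambda^d * h$alpha0 + below)
        if (length(nd$psi)) {
            m <- vapply(seq_along(nd$psi), function(i) {
                ck <- paste(c(k, i), collapse = ".")
                if (ck %in% keys) cnts$s[[ck]] else 0L
            }, numeric(1))
            later <- rev(cumsum(rev(m))) - m
            state$nodes[[k]]$psi <- .rbetaSafe(length(m), 1 + m,
                                                 h$gamma + later)
        }
    }
    state
}

## Hyperpriors keep the Laplace modes informative: mu ~ Gamma(8, scale 0.5)
## (mean 4, sd 1.4) so the +/- modes stay well separated on the logit scale,
## and Lambda ~ Gamma(2, scale 0.5) (mean 1). A diffuse prior on mu lets the
## chain collapse the mode separation to absorb mixed clones, which in turn
## makes further clone merging almost free -- a degenerate feedback that
## informative hyperpriors block.
.hyperTarget <- function(state, mu, Lambda) {
    if (mu <= 0 || Lambda <= 0) return(-Inf)
    p <- state$params
    p$mu <- mu; p$Lambda <- Lambda
    tot <- stats::dgamma(mu, shape = 8, scale = 0.5, log = TRUE) +
           stats::dgamma(Lambda, shape = 2, scale = 0.5, log = TRUE)
    for (k in names(state$nodes)) {
        nd <- state$nodes[[k]]
        if (k == "0")
            tot <- tot + rootLogPrior(nd$theta, mu, Lambda)
        else
            tot <- tot + transitionLogPdf(
                nd$theta, state$nodes[[parentKey(k)]]$theta, nd$t, p)
    }
    tot
}

.stepHypers <- function(state) {
    cfg <- state$config
    p <- state$params
    mu1 <- p$mu + stats::rnorm(1, 0, cfg$muStep)
    if (log(stats::runif(1)) <
        .hyperTarget(state, mu1, p$Lambda) -
        .hyperTarget(state, p$mu, p$Lambda))
        state$params$mu <- mu1
    p <- state$params
    L1 <- p$Lambda * exp(stats::rnorm(1, 0, cfg$LambdaStep))
    if (log(stats::runif(1)) <
        .hyperTarget(state, p$mu, L1) - .hyperTarget(state, p$mu, p$Lambda) +
        log(L1) - log(p$Lambda))
        state$params$Lambda <- L1
    state
}

#' One full Gibbs/Metropolis sweep
#'
#' Runs, in order: assignment resampling (with lazy candidate-node
#' instantiation), per-node parameter updates, branch-length updates,
#' conjugate stick resampling, kernel hyperparameter updates, and culling of
#' empty nodes. Deterministic given the RNG state.
#'
#' @param state a \code{"McmcState"} from \code{\link{initMcmcState}}.
#' @return The updated state.
#' @export
gibbsSweep <- function(state) {
    state$A <- rateMatrix(state$params$kind, state$params$betaM)
    state$jcache <- NULL
    scans <- max(1L, state$config$assignScans %||% 1L)
    for (scan in seq_len(scans)) {
        state <- .stepAssign(state)
        if (scan < scans) state <- .stepSticks(state)
    }
    state <- .stepTheta(state)
    state <- .stepBranch(state)
    state <- .stepSticks(state)
    if (state$config$updateHypers) state <- .stepHypers(state)
    state$nodes <- .cullNodes(state$nodes)
    state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## complete-data log joint including explicit assignments and stick priors
## (used by the swap move's Metropolis ratio)
.logJoint <- function(state) {
    nodes <- state$nodes
    keys <- names(nodes)
    h <- state$hypers
    pi <- .treeMass(nodes)$pi[keys]
    L <- .logLikMatrix(nodes, state$cache)
    tot <- 0
    for (ki in seq_along(keys)) {
        obs <- nodes[[keys[ki]]]$assigned
        if (!length(obs)) next
        if (pi[ki] <= 0) return(-Inf)
        cnt <- tabulate(state$cache$pat[obs], state$cache$U)
        tot <- tot + length(obs) * log(pi[ki]) + sum(cnt * L[ki, ])
    }
    for (k in keys) {
        nd <- nodes[[k]]
        d <- length(nd$path)
        tot <- tot + stats::dbeta(nd$nu, 1, h$lambda^d * h$alpha0, log = TRUE)
        if (length(nd$psi))
            tot <- tot + sum(stats::dbeta(nd$psi, 1, h$gamma, log = TRUE))
        if (k == "0")
            tot <- tot + rootLogPrior(nd$theta, state$params$mu,
                                      state$params$Lambda)
        else
            tot <- tot + stats::dexp(nd$t, 1, log = TRUE) +
                transitionLogPdf(nd$theta, nodes[[parentKey(k)]]$theta,
                                 nd$t, state$params)
    }
    tot
}

.swapNodes <- function(state, k1, k2) {
    for (f in c("theta", "assigned", "nu")) {
        tmp <- state$nodes[[k1]][[f]]
        state$nodes[[k1]][[f]] <- state$nodes[[k2]][[f]]
        state$nodes[[k2]][[f]] <- tmp
    }
    for (i in state$nodes[[k1]]$assigned) state$assign[i] <- k1
    for (i in state$nodes[[k2]]$assigned) state$assign[i] <- k2
    state
}

#' Swap-clone Metropolis move
#'
#' Proposes exchanging the parameters, assigned data and mass (depth-wise
#' stick) of two random instantiated nodes, accepts by a Metropolis ratio on
#' the full joint density, then resamples all stick variables from their
#' Beta full conditionals. States in which the root carries no observations
#' are invalid: further swaps involving the root are conducted until the
#' root is occupied again.
#'
#' @param state a \code{"McmcState"}.
#' @param force pair of node keys to propose (for diagnostics); default
#'   picks two distinct nodes uniformly at random.
#' @return The updated state. A single-node tree is returned unchanged.
#' @export
swapCloneMove <- function(state, force = NULL) {
    keys <- names(state$nodes)
    if (length(keys) < 2L) return(state)
    state$A <- rateMatrix(state$params$kind, state$params$betaM)
    state$jcache <- NULL
    pick <- if (is.null(force)) sample(keys, 2L) else force
    j0 <- .logJoint(state)
    cand <- .swapNodes(state, pick[1L], pick[2L])
    ## the exchanged depth sticks are re-proposed from their Beta full
    ## conditionals under the swapped allocation (with the proposal
    ## densities in the ratio); exchanging the raw stick values instead
    ## leaves them mismatched with the new subtree counts and the move is
    ## then rejected almost surely whenever the two nodes' masses differ
    logProp <- 0
    for (k in pick) {
        sp <- .stickParams(cand$nodes, k, state$hypers)
        nu1 <- .rbetaSafe(1, sp$nuA, sp$nuB)
        logProp <- logProp - stats::dbeta(nu1, sp$nuA, sp$nuB, log = TRUE)
        cand$nodes[[k]]$nu <- nu1
        sc <- .stickParams(state$nodes, k, state$hypers)
        logProp <- logProp + stats::dbeta(state$nodes[[k]]$nu, sc$nuA,
                                          sc$nuB, log = TRUE)
    }
    if (log(stats::runif(1)) < .logJoint(cand) - j0 + logProp) state <- cand
    state <- .stepSticks(state)
    ## repair: empty root states are invalid; conduct further swaps
    ## involving the root until it is occupied again (bounded; the
    ## assignment step maintains the constraint as well)
    guard <- 0L
    j0 <- NULL
    while (!length(state$nodes[["0"]]$assigned) && guard < 50L) {
        guard <- guard + 1L
        occ <- names(state$nodes)[vapply(state$nodes,
                       function(n) length(n$assigned) > 0L, logical(1))]
        other <- if (length(occ) == 1L) occ else sample(occ, 1L)
        if (is.null(j0)) j0 <- .logJoint(state)
        cand <- .swapNodes(state, "0", other)
        logProp <- 0
        for (k in c("0", other)) {
            sp <- .stickParams(cand$nodes, k, state$hypers)
            nu1 <- .rbetaSafe(1, sp$nuA, sp$nuB)
            logProp <- logProp - stats::dbeta(nu1, sp$nuA, sp$nuB,
                                              log = TRUE)
            cand$nodes[[k]]$nu <- nu1
            sc <- .stickParams(state$nodes, k, state$hypers)
            logProp <- logProp + stats::dbeta(state$nodes[[k]]$nu, sc$nuA,
                                              sc$nuB, log = TRUE)
        }
        if (log(stats::runif(1)) < .logJoint(cand) - j0 + logProp) {
            state <- cand
            state <- .stepSticks(state)
            j0 <- NULL
        }
    }
    if (!length(state$nodes[["0"]]$assigned)) {
        ## bounded fallback: pull one occupied node's data into the root
        occ <- names(state$nodes)[vapply(state$nodes,
                       function(n) length(n$assigned) > 0L, logical(1))]
        state <- .swapNodes(state, "0",
                            if (length(occ) == 1L) occ else sample(occ, 1L))
        state <- .stepSticks(state)
    }
    state$jcache <- NULL
    state
}

#' Complete-data log-likelihood with assignments marginalised
#'
#' Evaluates \eqn{\sum_n \log \sum_\epsilon \pi_\epsilon\,
#' p(x_n \mid \theta_\epsilon)} plus the parent-child transition terms for
#' all non-root nodes and the root prior, i.e. the joint density of data,
#' clone parameters and branch lengths given the sticks and
#' hyperparameters, with the assignment indicators integrated out against
#' the clone weights.
#'
#' @param state a \code{"McmcState"}.
#' @return The log-likelihood (a scalar).
#' @export
completeDataLogLik <- function(state) {
    nodes <- state$nodes
    keys <- names(nodes)
    pi <- .treeMass(nodes)$pi[keys]
    L <- .logLikMatrix(nodes, state$cache)
    W <- log(pi) + L
    mx <- apply(W, 2L, max)
    perPat <- mx + log(colSums(exp(sweep(W, 2L, mx))))
    tot <- sum(state$cache$counts * perPat)
    ## parameter terms run over the occupied skeleton: an empty leaf whose
    ## weight is negligible must not shift the value through its kernel
    ## factor (it is about to be culled anyway)
    kept <- names(.cullNodes(nodes))
    for (k in kept) {
        nd <- nodes[[k]]
        if (k == "0")
            tot <- tot + rootLogPrior(nd$theta, state$params$mu,
                                      state$params$Lambda)
        else
            tot <- tot + transitionLogPdf(
                nd$theta, nodes[[parentKey(k)]]$theta, nd$t, state$params)
    }
    tot
}

.snapshot <- function(state) {
    pi <- .treeMass(state$nodes)$pi
    list(nodes = state$nodes, assign = state$assign, pi = pi,
         mu = state$params$mu, Lambda = state$params$Lambda,
         logLik = completeDataLogLik(state),
         bigNodes = sum(pi > 0.01))
}

#' Run the MCMC sampler
#'
#' Executes \code{burnin + nKeep} sweeps (each sweep is one
#' \code{\link{gibbsSweep}} followed by \code{nSwaps}
#' \code{\link{swapCloneMove}}s), retaining every \code{thin}-th
#' post-burn-in state. Fully deterministic given \code{config$seed}.
#'
#' @param x a \code{\linkS4class{MarkerMatrix}}.
#' @param config an \code{\link{mcmcConfig}}.
#' @param verbose print progress every 500 sweeps.
#' @return A \code{\linkS4class{McmcTrace}}.
#' @export
runMcmc <- function(x, config = mcmcConfig(), verbose = FALSE) {
    set.seed(config$seed)
    state <- initMcmcState(x, config)
    total <- config$burnin + config$nKeep
    snaps <- vector("list", config$nKeep %/% config$thin)
    got <- 0L
    for (it in seq_len(total)) {
        state <- gibbsSweep(state)
        for (sw in seq_len(config$nSwaps)) state <- swapCloneMove(state)
        for (sm in seq_len(config$nSplitMerge %||% 0L))
            state <- splitMergeMove(state)
        if (it > config$burnin && (it - config$burnin) %% config$thin == 0L) {
            got <- got + 1L
            snaps[[got]] <- .snapshot(state)
        }
        if (verbose && it %% 500L == 0L)
            message(sprintf("sweep %d/%d: %d nodes", it, total,
                            length(state$nodes)))
    }
    new("McmcTrace", snapshots = snaps[seq_len(got)], nObs = state$cache$N,
        kind = state$kind, config = unclass(config))
}

#' Rebuild a TssbTree from a trace snapshot
#'
#' @param snapshot one element of \code{traceSnapshots(trace)}.
#' @param config the \code{\link{mcmcConfig}} of the run (for the
#'   hyperparameters).
#' @return A \code{\linkS4class{TssbTree}}.
#' @export
snapshotToTree <- function(snapshot, config = mcmcConfig()) {
    new("TssbTree", nodes = snapshot$nodes,
        hypers = list(lambda = config$lambda, alpha0 = config$alpha0,
                      gamma = config$gamma))
}
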