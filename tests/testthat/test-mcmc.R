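test_that("the default schedule retains exactly 10000 samples", {
    cfg <- mcmcConfig()
    expect_equal(cfg$burnin, 30000L)
    expect_equal(cfg$nKeep, 50000L)
    expect_equal(cfg$thin, 5L)
    expect_equal(cfg$nKeep %/% cfg$thin, 10000L)
    expect_equal(c(cfg$lambda, cfg$alpha0, cfg$gamma), c(2, 0.3, 0.1))
})

test_that("equilibrium frequencies are the non-missing entry means", {
    expect_equal(estimateEquilibrium(MarkerMatrix(rbind(c(1, 1), c(0, 0)))),
                 c(betaU = 0.5, betaM = 0.5))
    expect_equal(estimateEquilibrium(
        MarkerMatrix(rbind(c(1, NA), c(1, 0))))[["betaM"]], 2 / 3)
    expect_error(estimateEquilibrium(MarkerMatrix(matrix(1, 2, 2))),
                 "degenerate")
    expect_error(estimateEquilibrium(MarkerMatrix(matrix(NA_real_, 2, 2))),
                 "missing")
})

test_that("a sweep with a frozen RNG is bitwise reproducible and conserves
           observations", {
    set.seed(1)
    fx <- makeFixture("polyclonal_low")
    sim <- sampleObservations(fx, 60)
    cfg <- mcmcConfig(burnin = 0, nKeep = 1, seed = 5)
    st <- initMcmcState(sim$data, cfg)
    set.seed(5); a <- gibbsSweep(st)
    set.seed(5); b <- gibbsSweep(st)
    expect_identical(a, b)
    # every observation assigned to exactly one instantiated node
    allObs <- sort(unname(unlist(lapply(a$nodes, `[[`, "assigned"))))
    expect_equal(allObs, seq_len(60))
    expect_true(all(a$assign %in% names(a$nodes)))
})

test_that("trace length follows the burnin/keep/thin arithmetic and the
           seed makes runs identical", {
    set.seed(2)
    sim <- sampleObservations(makeFixture("monoclonal"), 40)
    cfg <- mcmcConfig(burnin = 0, nKeep = 10, thin = 5, seed = 9)
    tr <- runMcmc(sim$data, cfg)
    expect_equal(nSamples(tr), 2)
    tr2 <- runMcmc(sim$data, cfg)
    expect_identical(lapply(traceSnapshots(tr), `[[`, "assign"),
                     lapply(traceSnapshots(tr2), `[[`, "assign"))
    expect_identical(vapply(traceSnapshots(tr), `[[`, numeric(1), "logLik"),
                     vapply(traceSnapshots(tr2), `[[`, numeric(1), "logLik"))
})

test_that("root-only chain targets the analytic single-site posterior", {
    # one site, fixed kernel, tree growth disabled: the chain over the root
    # parameter must match the quadrature posterior
    # p(theta | x) ~ Laplace(theta; -mu, Lambda) * Bernoulli(x | sigmoid)
    x <- MarkerMatrix(matrix(c(1, 0, 1), 3, 1))
    cfg <- mcmcConfig(burnin = 200, nKeep = 4000, thin = 1, seed = 3,
                      maxDepth = 0, updateHypers = FALSE, muInit = 1,
                      LambdaInit = 1, nSwaps = 0L)
    tr <- runMcmc(x, cfg)
    draws <- vapply(traceSnapshots(tr),
                    function(s) s$nodes[["0"]]$theta, numeric(1))
    grid <- seq(-8, 8, by = 0.01)
    post <- exp(dlaplaceLog(grid, -1, 1) +
                2 * log(plogis(grid)) + log(1 - plogis(grid)))
    post <- post / sum(post * 0.01)
    postMean <- sum(grid * post) * 0.01
    postSd <- sqrt(sum((grid - postMean)^2 * post) * 0.01)
    mcse <- postSd / sqrt(200)   # conservative effective sample size
    expect_lt(abs(mean(draws) - postMean), 4 * mcse)
    expect_lt(abs(sd(draws) - postSd) / postSd, 0.2)
})

test_that("two well-separated clones are recovered with confident
           co-clustering", {
    set.seed(6)
    X <- rbind(matrix(0, 25, 8), matrix(1, 25, 8))
    X[1, 1] <- 1; X[30, 2] <- 0   # a little noise keeps betaM off 0/1 bounds
    tr <- runMcmc(MarkerMatrix(X),
                  mcmcConfig(burnin = 300, nKeep = 400, thin = 5, seed = 8))
    psm <- posteriorSimilarity(tr)
    within1 <- psm[2:25, 2:25][lower.tri(psm[2:25, 2:25])]
    across <- psm[2:25, 31:50]
    expect_gt(mean(within1), 0.75)
    expect_lt(mean(across), 0.1)
    lab <- mpearSummary(psm)
    expect_equal(vMeasure(rep(1:2, each = 25), lab), 1)
})

test_that("complete-data log-likelihood matches exhaustive enumeration", {
    # 2 observations, 1 site, a fixed 2-node tree: marginalising the
    # assignments must equal the brute-force sum over all 2^2 combinations
    x <- MarkerMatrix(matrix(c(1, 0), 2, 1))
    cfg <- mcmcConfig(seed = 1)
    st <- initMcmcState(x, cfg)
    st$nodes <- list(
        "0" = cloneTree:::.newNode(integer(0), nu = 0.6, psi = 0.8,
                                   theta = -1.2, assigned = 1L),
        "0.1" = cloneTree:::.newNode(1L, nu = 0.9, theta = 1.7, t = 0.7,
                                     assigned = 2L))
    st$assign <- c("0", "0.1")
    got <- completeDataLogLik(st)

    pi <- cloneTree:::.treeMass(st$nodes)$pi
    th <- c(-1.2, 1.7)
    lik <- function(xv, thv) plogis(thv)^xv * (1 - plogis(thv))^(1 - xv)
    bruteData <- 0
    for (a1 in 1:2) for (a2 in 1:2)
        bruteData <- bruteData + pi[a1] * lik(1, th[a1]) *
                                 pi[a2] * lik(0, th[a2])
    brute <- log(bruteData) +
        rootLogPrior(-1.2, st$params$mu, st$params$Lambda) +
        transitionLogPdf(1.7, -1.2, 0.7, st$params)
    expect_equal(got, unname(brute), tolerance = 1e-10)

    # single-clone tree reduces to root prior plus local likelihoods
    st1 <- initMcmcState(x, cfg)
    st1$nodes[["0"]]$nu <- 1 - 1e-12
    expect_equal(completeDataLogLik(st1),
                 rootLogPrior(st1$nodes[["0"]]$theta, st1$params$mu,
                              st1$params$Lambda) +
                 localLogLik(1, st1$nodes[["0"]]$theta) +
                 localLogLik(0, st1$nodes[["0"]]$theta),
                 tolerance = 1e-9)

    # adding an empty node with negligible weight barely moves the value
    st2 <- st
    st2$nodes[["0.2"]] <- cloneTree:::.newNode(2L, nu = 0.5, theta = 0.3,
                                               t = 1)
    st2$nodes[["0"]]$psi <- c(0.8, 1e-13)
    expect_lt(abs(completeDataLogLik(st2) - got), 1e-9)
})

test_that("swap-clone move conserves observations, keeps the root occupied,
           and accepts symmetric swaps", {
    set.seed(10)
    sim <- sampleObservations(makeFixture("polyclonal_low"), 80)
    cfg <- mcmcConfig(burnin = 0, nKeep = 1, seed = 4)
    st <- initMcmcState(sim$data, cfg)
    set.seed(4)
    for (i in 1:10) st <- gibbsSweep(st)
    for (i in 1:30) {
        st <- swapCloneMove(st)
        allObs <- sort(unname(unlist(lapply(st$nodes, `[[`, "assigned"))))
        expect_equal(allObs, seq_len(80))
        expect_gt(length(st$nodes[["0"]]$assigned), 0)
    }

    # two nodes with identical theta, data counts and mass: the proposal is
    # a symmetry of the state, so it is always accepted
    x <- MarkerMatrix(matrix(c(1, 0, 1, 0), 4, 2))
    st2 <- initMcmcState(x, mcmcConfig(seed = 1))
    st2$nodes <- list(
        "0" = cloneTree:::.newNode(integer(0), nu = 0.4, psi = c(0.5, 0.5),
                                   theta = c(0, 0), assigned = 1:2),
        "0.1" = cloneTree:::.newNode(1L, nu = 0.7, theta = c(1, -1), t = 1,
                                     assigned = 3L),
        "0.2" = cloneTree:::.newNode(2L, nu = 0.7, theta = c(1, -1), t = 1,
                                     assigned = 4L))
    st2$assign <- c("0", "0", "0.1", "0.2")
    st2$A <- rateMatrix(st2$params$kind, st2$params$betaM)
    j0 <- cloneTree:::.logJoint(st2)
    swapped <- cloneTree:::.swapNodes(st2, "0.1", "0.2")
    expect_equal(cloneTree:::.logJoint(swapped), j0, tolerance = 1e-9)

    # single-node tree: no-op
    st3 <- initMcmcState(x, mcmcConfig(seed = 1))
    expect_identical(swapCloneMove(st3)$nodes, st3$nodes)
})

test_that("posterior similarity has unit diagonal, symmetry and the exact
           co-clustering fractions", {
    snap <- function(lab) list(assign = lab, nodes = list(), pi = 1,
                               logLik = 0, bigNodes = 1)
    tr <- new("McmcTrace",
              snapshots = list(snap(c("a", "a", "b")),
                               snap(c("a", "b", "b"))),
              nObs = 3, kind = "methylation", config = list())
    psm <- posteriorSimilarity(tr)
    expect_equal(diag(psm), rep(1, 3))
    expect_equal(psm, t(psm))
    expect_equal(psm[1, 2], 0.5)
    expect_equal(psm[2, 3], 0.5)
    expect_equal(psm[1, 3], 0)
    expect_error(posteriorSimilarity(
        new("McmcTrace", snapshots = list(), nObs = 0, kind = "snv",
            config = list())), "empty")
})

test_that("split-merge move conserves observations, is reproducible, and
           separates a clearly mixed clone", {
    set.seed(3)
    sim <- sampleObservations(makeFixture("polyclonal_low"), 80)
    cfg <- mcmcConfig(burnin = 0, nKeep = 1, seed = 4)
    st <- initMcmcState(sim$data, cfg)
    set.seed(4)
    for (i in 1:10) st <- gibbsSweep(st)
    set.seed(5); a <- splitMergeMove(st)
    set.seed(5); b <- splitMergeMove(st)
    expect_identical(a$nodes, b$nodes)
    for (i in 1:40) {
        st <- splitMergeMove(st)
        allObs <- sort(unname(unlist(lapply(st$nodes, `[[`, "assigned"))))
        expect_equal(allObs, seq_len(80))
    }

    # a root clone holding two very distinct marker groups is split within
    # a modest number of attempts
    X <- rbind(matrix(0, 30, 8), matrix(1, 30, 8))
    X[1, 1] <- 1; X[60, 8] <- 0
    st2 <- initMcmcState(MarkerMatrix(X), cfg)
    st2$nodes[["0"]]$theta <- rep(0, 8)   # blurred fit of the mixture
    set.seed(11)
    for (i in 1:50) st2 <- splitMergeMove(st2)
    expect_gt(length(st2$nodes), 1)
    kid <- setdiff(names(st2$nodes), "0")[1]
    grp <- st2$nodes[[kid]]$assigned
    expect_true(all(grp <= 30) || all(grp > 30))
})
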