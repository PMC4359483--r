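test_that("v-measure matches independently computed reference values", {
    expect_equal(vMeasure(c(1, 1, 2, 2), c(9, 9, 2, 2)), 1)
    expect_equal(vMeasure(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
    # all-singleton prediction: perfect homogeneity, imperfect completeness
    expect_equal(vMeasure(c(1, 1, 2, 2, 3, 3), 1:6), 0.7601875334318687)
    # reference values frozen from an independent implementation
    expect_equal(vMeasure(c(rep("A", 4), rep("B", 4)),
                          c(1, 1, 1, 2, 2, 2, 2, 2)), 0.5615896365639194)
    expect_equal(vMeasure(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 3, 3)),
                 0.5158037429793889)
    expect_equal(vMeasure(c(1, 2, 1, 2, 1, 2, 3, 3), c(1, 1, 2, 2, 3, 3, 4, 4)),
                 0.4556106521909716)
    expect_error(vMeasure(1:3, 1:4), "length")
})

test_that("v-measure is invariant under label permutation of either side", {
    set.seed(3)
    a <- sample(1:3, 20, TRUE)
    b <- sample(1:4, 20, TRUE)
    relab <- c(7, 5, 9)
    expect_equal(vMeasure(relab[a], b), vMeasure(a, b))
    relabB <- c("w", "x", "y", "z")
    expect_equal(vMeasure(a, relabB[b]), vMeasure(a, b))
    # symmetric in its arguments (homogeneity and completeness swap)
    expect_equal(vMeasure(a, b), vMeasure(b, a))
})

test_that("hand-computed v-measure from conditional entropies", {
    # true (A,A,A,A,B,B,B,B), pred (1,1,1,2,2,2,2,2):
    # H(T)=H(P)=log-ish values computed directly from the contingency table
    n <- 8
    tab <- rbind(c(3, 1), c(0, 4))
    Ht <- -sum(rowSums(tab) / n * log(rowSums(tab) / n))
    Hp <- -sum(colSums(tab) / n * log(colSums(tab) / n))
    # column-wise: col1 = (3,0) has zero entropy; col2 = (1,4)
    HtGivenP <- 5/8 * (-(1/5 * log(1/5) + 4/5 * log(4/5)))
    HpGivenT <- 4/8 * (-(3/4 * log(3/4) + 1/4 * log(1/4)))
    h <- 1 - HtGivenP / Ht
    c <- 1 - HpGivenT / Hp
    expect_equal(vMeasure(rep(c("A", "B"), each = 4),
                          c(1, 1, 1, 2, 2, 2, 2, 2)),
                 2 * h * c / (h + c))
})

test_that("consensus shortest-path distance reproduces hand-built cases", {
    mkGraph <- function(edges, pats) {
        rownames(pats) <- letters[seq_len(nrow(pats))]
        cloneGraph(edges, pats,
                   setNames(rep(1, nrow(pats)), rownames(pats)))
    }
    pats <- rbind(c(0, 0), c(0, 1), c(1, 1))
    path <- mkGraph(rbind(c("a", "b"), c("b", "c")), pats)
    star <- mkGraph(rbind(c("a", "b"), c("a", "c")), pats)

    expect_equal(consensusSpDistance(path, list(path)), 0)
    # path a-b-c vs star a-b, a-c: |1-1| + |1-2| + |2-1| = 2
    expect_equal(consensusSpDistance(path, list(star)), 2)
    # symmetric under swapping roles
    expect_equal(consensusSpDistance(star, list(path)), 2)

    # oracle: breadth-first hop distances computed independently
    ids <- letters[1:3]
    Dp <- bfsDistances(rbind(c("a", "b"), c("b", "c")), ids)
    Ds <- bfsDistances(rbind(c("a", "b"), c("a", "c")), ids)
    expect_equal(sum(abs(Ds[lower.tri(Ds)] - Dp[lower.tri(Dp)])), 2)

    # empty shared set is an explicit error
    other <- mkGraph(rbind(c("a", "b")), rbind(c(1, 0), c(0, 0)) + 2)
    expect_error(consensusSpDistance(path, list(other)), "shared")
})

test_that("consensus distance consumes fixtures, inferred trees and
           baseline fits", {
    fx <- makeFixture("monoclonal")
    g <- asCloneGraph(fx)
    expect_s3_class(g, "cloneGraph")
    expect_equal(consensusSpDistance(fx, list(fx)), 0)

    # an inferred tree whose state calls reproduce the fixture genotypes
    mu <- 4
    nodes <- list(
        "0" = cloneTree:::.newNode(integer(0), nu = 0.1,
                                   psi = 0.99,
                                   theta = rep(-mu, 8), assigned = 1:2),
        "0.1" = cloneTree:::.newNode(1L, nu = 0.95,
                                     theta = c(rep(mu, 4), rep(-mu, 4)),
                                     t = 1, assigned = 3:20))
    tssb <- new("TssbTree", nodes = nodes,
                hypers = list(lambda = 2, alpha0 = 0.3, gamma = 0.1))
    expect_equal(consensusSpDistance(fx, list(tssb)), 0)

    fit <- new("BaselineFit", method = "hierarchical",
               labels = rep(1:2, each = 5),
               methyltypes = fx@genotypes, edges = cbind(1L, 2L), root = 1L)
    rownames(fit@methyltypes) <- NULL
    expect_equal(consensusSpDistance(fx, list(fit)), 0)
})

test_that("duplicate patterns map to the highest-mass node", {
    pats <- rbind(c(0, 0), c(1, 1), c(1, 1))
    rownames(pats) <- c("r", "x", "y")
    g <- cloneGraph(rbind(c("r", "x"), c("x", "y")), pats,
                    c(r = 0.5, x = 0.1, y = 0.4))
    mapped <- cloneTree:::.patternNodes(g)
    expect_equal(unname(mapped[["11"]]), "y")
})

test_that("tree summaries report depth, clone counts and level mass", {
    tr <- makeHandTree()
    s <- treeSummary(tr)
    w <- handTreeWeights()
    expect_equal(s$maxDepth, 1)              # occupied clones at depth 0, 1
    expect_equal(s$nClones, 2)
    expect_equal(s$totalBranchLength, 0.5 + 0.3 + 0.2)
    expect_equal(unname(s$levelMass["0"]), unname(w["0"]))
    expect_equal(unname(s$levelMass["1"]), unname(w["0.1"] + w["0.2"]))
    expect_equal(sum(s$levelMass), sum(w))

    # big-clone rule is strictly greater than 1%
    tr2 <- makeHandTree(nuRoot = 0.011, nu1 = 1e-4)
    pi2 <- cloneWeights(tr2)
    s2 <- treeSummary(tr2)
    expect_equal(s2$nBigClones, sum(pi2 > 0.01))

    rootOnly <- new("TssbTree",
        nodes = list("0" = cloneTree:::.newNode(integer(0), nu = 1 - 1e-12,
                                                theta = 0, assigned = 1L)),
        hypers = list(lambda = 2, alpha0 = 0.3, gamma = 0.1))
    s3 <- treeSummary(rootOnly)
    expect_equal(s3$maxDepth, 0)
    expect_equal(as.numeric(s3$levelMass), 1, tolerance = 1e-9)
})

test_that("symmetrised KL divergence is zero at equality, symmetric, and
           matches direct evaluation", {
    expect_equal(symmetrizedKl(c(0.3, 0.7), c(0.3, 0.7)), 0, tolerance = 1e-6)
    p <- c(0.5, 0.5); q <- c(0.9, 0.1)
    direct <- sum(p * log(p / q)) + sum(q * log(q / p))
    expect_equal(symmetrizedKl(p, q), direct, tolerance = 1e-6)
    expect_equal(symmetrizedKl(p, q), symmetrizedKl(q, p))
    # padding to a common support
    expect_gt(symmetrizedKl(c(1), c(0.5, 0.5)), 0)
})
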