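test_that("clone label depth and parent follow the addressing scheme", {
    expect_equal(cloneDepth(c(1, 2)), 2)
    expect_equal(cloneDepth(integer(0)), 0)
    expect_equal(cloneDepth(c(3, 1, 1, 4)), 4)
    expect_equal(parentLabel(c(1, 2)), 1)
    expect_equal(parentLabel(1L), integer(0))
    expect_equal(parentLabel(c(2, 5, 1)), c(2, 5))
    expect_error(parentLabel(integer(0)), "root")
    expect_error(cloneDepth(c(0, 1)), "positive")
})

test_that("branch weights multiply the unbroken sibling sticks", {
    expect_equal(branchWeight(0.7), 0.7)
    expect_equal(branchWeight(0.5, 0.5), 0.25)
    expect_equal(branchWeight(1.0, c(0.2, 0.3)), 1.0 * 0.8 * 0.7)
    expect_error(branchWeight(1.2), "\\[0,1\\]")
})

test_that("clone weights match direct stick-breaking substitution", {
    # single root
    rootOnly <- new("TssbTree",
        nodes = list("0" = cloneTree:::.newNode(integer(0), nu = 0.4,
                                                theta = 0, assigned = 1L)),
        hypers = list(lambda = 2, alpha0 = 0.3, gamma = 0.1))
    w <- cloneWeights(rootOnly)
    expect_equal(unname(w[["0"]]), 0.4)
    expect_equal(attr(w, "residual"), 0.6)

    # root nu=0.5 with one child taking the whole remainder
    tr <- makeHandTree(nuRoot = 0.5, nu1 = 1, psiRoot = 1, psi1 = numeric(0))
    tr@nodes[["0.2"]] <- NULL
    tr@nodes[["0.1.1"]] <- NULL
    tr@nodes[["0"]]$psi <- 1
    tr@nodes[["0.1"]]$psi <- numeric(0)
    w <- cloneWeights(tr)
    expect_equal(unname(w[c("0", "0.1")]), c(0.5, 0.5))
    expect_equal(sum(w) + attr(w, "residual"), 1)

    # general hand tree against independent substitution
    tr <- makeHandTree()
    expect_equal(cloneWeights(tr)[names(handTreeWeights())],
                 handTreeWeights(), tolerance = 1e-12)
})

test_that("weights plus un-instantiated residual always account for all mass", {
    set.seed(5)
    for (rep in 1:20) {
        pr <- samplePriorTree(list(lambda = 2, alpha0 = 0.3, gamma = 0.1),
                              nObs = sample(1:30, 1))
        w <- cloneWeights(pr$tree)
        expect_true(all(w >= 0))
        expect_equal(sum(w) + attr(w, "residual"), 1, tolerance = 1e-12)
    }
})

test_that("instantiation drives the residual below a strict tolerance", {
    # fast-depleting sticks (deep nu -> 1, dominant first child) reach full
    # stick depletion quickly; the weights must then account for all but
    # 1e-10 of the mass without exceeding 1
    set.seed(9)
    pr <- samplePriorTree(list(lambda = 0.2, alpha0 = 0.3, gamma = 0.05),
                          nObs = 5)
    tr <- expandTree(pr$tree, evolutionParams("methylation", 0.5),
                     tol = 1e-10, maxNodes = 100000L)
    w <- cloneWeights(tr)
    expect_lt(attr(w, "residual"), 1e-10)
    expect_true(sum(w) >= 1 - 1e-10 && sum(w) <= 1 + 1e-12)
})

test_that("the residual shrinks monotonically under deepening instantiation", {
    set.seed(12)
    pr <- samplePriorTree(list(lambda = 2, alpha0 = 0.3, gamma = 0.1),
                          nObs = 5)
    prm <- evolutionParams("methylation", 0.5)
    res <- vapply(c(50, 200, 800), function(cap) {
        set.seed(77)   # same draw sequence, so deeper caps nest shallower ones
        w <- cloneWeights(expandTree(pr$tree, prm, tol = 1e-12,
                                     maxNodes = cap))
        expect_equal(sum(w) + attr(w, "residual"), 1, tolerance = 1e-9)
        attr(w, "residual")
    }, numeric(1))
    expect_true(all(diff(res) < 0))
    expect_lt(res[3], 0.01)
})

test_that("prior root weight matches its Beta(1, alpha0) mean", {
    set.seed(31)
    roots <- replicate(4000, {
        pr <- samplePriorTree(list(lambda = 2, alpha0 = 0.3, gamma = 0.1),
                              nObs = 1, M = 1)
        pr$tree@nodes[["0"]]$nu
    })
    expect_equal(mean(roots), 1 / 1.3, tolerance = 0.02)
})

test_that("assignment frequencies agree with the drawn clone weights", {
    set.seed(13)
    pr <- samplePriorTree(list(lambda = 2, alpha0 = 0.3, gamma = 0.1),
                          nObs = 1e5, M = 1)
    w <- cloneWeights(pr$tree)
    counts <- table(factor(pr$assignments, levels = names(w)))
    keep <- w * 1e5 >= 5
    expect_gt(sum(keep), 1)
    p <- w[keep] / sum(w[keep])
    test <- suppressWarnings(
        chisq.test(as.numeric(counts[keep]), p = p, rescale.p = TRUE))
    expect_gt(test$p.value, 1e-4)
})

test_that("prior trees have finite mean depth under the depth-decay prior", {
    set.seed(17)
    depths <- replicate(500, {
        pr <- samplePriorTree(list(lambda = 2, alpha0 = 0.3, gamma = 0.1),
                              nObs = 3, M = 1)
        max(vapply(pr$tree@nodes, function(n) length(n$path), integer(1)))
    })
    expect_true(is.finite(mean(depths)))
    expect_lt(mean(depths), 20)
})

test_that("repeated prior draws under a fixed seed are identical", {
    h <- list(lambda = 2, alpha0 = 0.3, gamma = 0.1)
    set.seed(99); a <- samplePriorTree(h, nObs = 50)
    set.seed(99); b <- samplePriorTree(h, nObs = 50)
    expect_identical(a$assignments, b$assignments)
    expect_identical(a$tree@nodes, b$tree@nodes)
})

test_that("culling removes only empty leaf-side nodes and is idempotent", {
    tr <- makeHandTree()
    # 0.2 empty leaf -> culled; 0.1.1 empty leaf -> culled; occupied kept
    culled <- cullEmpty(tr)
    expect_setequal(names(culled@nodes), c("0", "0.1"))

    # empty node with an occupied descendant is retained
    tr2 <- makeHandTree()
    tr2@nodes[["0.1"]]$assigned <- integer(0)
    tr2@nodes[["0.1.1"]]$assigned <- 5L
    culled2 <- cullEmpty(tr2)
    expect_true(all(c("0", "0.1", "0.1.1") %in% names(culled2@nodes)))
    expect_false("0.2" %in% names(culled2@nodes))

    expect_identical(cullEmpty(culled2)@nodes, culled2@nodes)
})

test_that("culling preserves the weights of surviving clones", {
    tr <- makeHandTree()
    w0 <- cloneWeights(tr)
    w1 <- cloneWeights(cullEmpty(tr))
    expect_equal(w1, w0[names(w1)], ignore_attr = TRUE)
})

test_that("malformed trees are rejected", {
    nodes <- list(
        "0" = cloneTree:::.newNode(integer(0), nu = 0.5, theta = 0),
        "0.1.1" = cloneTree:::.newNode(c(1L, 1L), nu = 0.5, theta = 0,
                                       t = 1))
    expect_error(
        validObject(new("TssbTree", nodes = nodes,
                        hypers = list(lambda = 2, alpha0 = 0.3, gamma = 0.1))),
        "prefix")
})
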