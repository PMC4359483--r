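# Shared helpers: hand-built trees/states, brute-force oracles, and a cache
# for the expensive chain runs shared by the acceptance checks.

# a small deterministic tree: root -> (1, 2), 1 -> (1.1)
makeHandTree <- function(nuRoot = 0.5, nu1 = 0.6, nu2 = 0.8, nu11 = 1,
                         psiRoot = c(0.7, 0.9), psi1 = 0.5, M = 2) {
    nodes <- list(
        "0" = cloneTree:::.newNode(integer(0), nu = nuRoot, psi = psiRoot,
                                   theta = rep(0, M),
                                   assigned = 1L),
        "0.1" = cloneTree:::.newNode(1L, nu = nu1, psi = psi1,
                                     theta = rep(1, M), t = 0.5,
                                     assigned = 2L),
        "0.2" = cloneTree:::.newNode(2L, nu = nu2, theta = rep(-1, M),
                                     t = 0.3),
        "0.1.1" = cloneTree:::.newNode(c(1L, 1L), nu = nu11,
                                       theta = rep(2, M), t = 0.2))
    new("TssbTree", nodes = nodes,
        hypers = list(lambda = 2, alpha0 = 0.3, gamma = 0.1))
}

# expected weights of makeHandTree by direct substitution in the
# stick-breaking formula (independent of the package's traversal)
handTreeWeights <- function(nuRoot = 0.5, nu1 = 0.6, nu2 = 0.8, nu11 = 1,
                            psiRoot = c(0.7, 0.9), psi1 = 0.5) {
    rest <- 1 - nuRoot
    phi1 <- psiRoot[1]
    phi2 <- psiRoot[2] * (1 - psiRoot[1])
    c("0" = nuRoot,
      "0.1" = rest * phi1 * nu1,
      "0.2" = rest * phi2 * nu2,
      "0.1.1" = rest * phi1 * (1 - nu1) * psi1 * nu11)
}

# enumerate all set partitions of 1..n (restricted growth strings)
allPartitions <- function(n) {
    out <- list()
    rec <- function(labels, maxUsed) {
        i <- length(labels) + 1L
        if (i > n) {
            out[[length(out) + 1L]] <<- labels
            return()
        }
        for (v in seq_len(maxUsed + 1L))
            rec(c(labels, v), max(maxUsed, v))
    }
    rec(integer(0), 0L)
    out
}

# naive per-point silhouette from a distance matrix
naiveSilhouette <- function(D, labels) {
    D <- as.matrix(D)
    n <- nrow(D)
    vapply(seq_len(n), function(i) {
        own <- labels == labels[i]
        a <- if (sum(own) > 1) mean(D[i, own & seq_len(n) != i]) else 0
        b <- min(vapply(setdiff(unique(labels), labels[i]), function(k)
            mean(D[i, labels == k]), numeric(1)))
        if (sum(own) == 1) 0 else (b - a) / max(a, b)
    }, numeric(1))
}

# breadth-first hop distances on an undirected edge list over node ids
bfsDistances <- function(edges, ids) {
    n <- length(ids)
    D <- matrix(Inf, n, n, dimnames = list(ids, ids))
    adj <- setNames(rep(list(character(0)), n), ids)
    if (nrow(edges)) for (r in seq_len(nrow(edges))) {
        a <- edges[r, 1]; b <- edges[r, 2]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
    }
    for (s in ids) {
        D[s, s] <- 0
        queue <- s
        while (length(queue)) {
            u <- queue[1]; queue <- queue[-1]
            for (w in adj[[u]]) if (!is.finite(D[s, w])) {
                D[s, w] <- D[s, u] + 1
                queue <- c(queue, w)
            }
        }
    }
    D
}

# cache for chain runs shared across acceptance test blocks
.runCache <- new.env(parent = emptyenv())

cachedRun <- function(name, fun) {
    if (is.null(.runCache[[name]])) .runCache[[name]] <- fun()
    .runCache[[name]]
}

# one benchmark replicate: simulate, run the chain, summarise
benchmarkRun <- function(mode, n, error, seed,
                         burnin = 2000, nKeep = 3000, thin = 5) {
    set.seed(seed)
    fx <- makeFixture(mode)
    sim <- sampleObservations(fx, n)
    noisy <- if (error > 0) addFlipNoise(sim$data, error) else sim$data
    cfg <- mcmcConfig(burnin = burnin, nKeep = nKeep, thin = thin,
                      seed = seed + 1L)
    trace <- runMcmc(noisy, cfg)
    list(fixture = fx, data = noisy, trueLabels = sim$labels,
         trace = trace, config = cfg)
}
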