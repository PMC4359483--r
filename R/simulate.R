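## Benchmark simulator: five canonical ground-truth clone trees and noisy
## binary observations sampled from them.
##
## The five modes mirror the classic modes of tumor evolution: a monoclonal
## tumor (healthy root plus one tumor clone), three polyclonal trees of
## increasing complexity, and a mutator phenotype (star tree with many small
## leaf clones). Genotypes are built over M sites by toggling a fixed set of
## sites along each edge, so sibling clones can differ in as little as a
## single site and clone sizes are highly asymmetric -- the feature that
## makes the low-frequency clones genuinely hard to separate.

## per-mode edge tables: clone label path (dot string, "" = root), relative
## frequency, and the sites toggled relative to the parent genotype
.fixtureSpec <- function(mode) {
    switch(mode,
        monoclonal = list(
            list("",  0.10, integer(0)),
            list("1", 0.90, c(1L, 2L, 3L, 4L))),
        polyclonal_low = list(
            list("",    0.05, integer(0)),
            list("1",   0.55, c(1L, 2L)),
            list("2",   0.10, c(5L, 6L)),
            list("1.1", 0.15, 3L),
            list("1.2", 0.10, 4L),
            list("2.1", 0.05, 7L)),
        polyclonal_medium = {
            base <- .fixtureSpec("polyclonal_low")
            extra <- list(
                list("1.1.1", 0.03, 5L),
                list("1.1.2", 0.03, 6L),
                list("1.1.3", 0.03, 7L),
                list("1.2.1", 0.02, 5L),
                list("1.2.2", 0.02, 6L))
            scale <- 1 - sum(vapply(extra, `[[`, numeric(1), 2L))
            base <- lapply(base, function(b) { b[[2L]] <- b[[2L]] * scale; b })
            c(base, extra)
        },
        polyclonal_high = {
            base <- .fixtureSpec("polyclonal_medium")
            extra <- list(
                list("1.3",     0.02, 8L),
                list("2.2",     0.02, 8L),
                list("3",       0.02, c(3L, 4L)),
                list("3.1",     0.02, 1L),
                list("2.1.1",   0.02, 1L),
                list("1.1.1.1", 0.02, 4L),
                list("1.2.1.1", 0.02, 7L))
            all <- c(base, extra)
            tot <- sum(vapply(all, `[[`, numeric(1), 2L))
            lapply(all, function(b) { b[[2L]] <- b[[2L]] / tot; b })
        },
        mutator = {
            leaves <- lapply(seq_len(12L), function(k) {
                flips <- if (k <= 8L) k else c(k - 8L, k - 7L)
                list(as.character(k), 0.9 / 12, as.integer(flips))
            })
            c(list(list("", 0.10, integer(0))), leaves)
        },
        stop(sprintf("unknown fixture mode '%s'", mode)))
}

#' Ground-truth clone trees for the simulation benchmark
#'
#' Builds one of the five canonical fixtures: \code{monoclonal} (an all-zero
#' healthy root and a single tumor clone), \code{polyclonal_low} (a
#' three-layer tree of 6 clones with a dominant mid-layer clone and minor
#' siblings), \code{polyclonal_medium} (\code{polyclonal_low} plus a fourth
#' level of five small clones with frequencies 0.03, 0.03, 0.03, 0.02,
#' 0.02), \code{polyclonal_high} (extended to 18 clones, the added ones at
#' frequency about 0.02, renormalised to sum to one) and \code{mutator}
#' (a star tree: root plus 12 small leaf clones). Genotypes are assigned
#' deterministically over \code{M} sites by per-edge site toggles; every
#' child differs from its parent in at least one site and some siblings
#' differ in exactly one.
#'
#' @param mode one of \code{"monoclonal"}, \code{"polyclonal_low"},
#'   \code{"polyclonal_medium"}, \code{"polyclonal_high"}, \code{"mutator"}.
#' @param M number of marker sites (at least 8).
#' @return A \code{\linkS4class{CloneFixture}}.
#' @examples
#' makeFixture("monoclonal")
#' sum(makeFixture("polyclonal_high")@frequencies)  # 1
#' @export
makeFixture <- function(mode = c("monoclonal", "polyclonal_low",
                                 "polyclonal_medium", "polyclonal_high",
                                 "mutator"), M = 8L) {
    mode <- match.arg(mode)
    if (M < 8L) stop("fixtures are defined over at least 8 sites")
    spec <- .fixtureSpec(mode)
    paths <- lapply(spec, function(s)
        if (nzchar(s[[1L]])) as.integer(strsplit(s[[1L]], ".", fixed = TRUE)[[1L]])
        else integer(0))
    keys <- vapply(paths, labelKey, character(1))
    geno <- matrix(0, length(spec), M)
    rownames(geno) <- keys
    for (i in seq_along(spec)) {
        p <- paths[[i]]
        g <- if (length(p)) geno[labelKey(parentLabel(p)), ] else rep(0, M)
        flips <- spec[[i]][[3L]]
        g[flips] <- 1 - g[flips]
        geno[i, ] <- g
    }
    if (anyDuplicated(apply(geno, 1L, paste, collapse = "")))
        stop("internal error: fixture genotypes not unique")
    new("CloneFixture", mode = mode, labels = paths,
        frequencies = vapply(spec, `[[`, numeric(1), 2L), genotypes = geno)
}

#' Sample observations from a fixture
#'
#' Draws clone memberships i.i.d. from the fixture's clone frequencies and
#' emits each observation as an exact copy of its clone's genotype (add
#' measurement noise separately with \code{\link{addFlipNoise}}).
#'
#' @param fixture a \code{\linkS4class{CloneFixture}}.
#' @param n number of observations.
#' @param kind marker kind of the returned matrix.
#' @return List with \code{data} (a \code{\linkS4class{MarkerMatrix}}) and
#'   \code{labels} (character vector of true clone keys per observation).
#' @export
sampleObservations <- function(fixture, n, kind = c("methylation", "snv")) {
    kind <- match.arg(kind)
    if (n < 1) stop("n must be at least 1")
    idx <- sample.int(length(fixture@labels), n, replace = TRUE,
                      prob = fixture@frequencies)
    X <- fixture@genotypes[idx, , drop = FALSE]
    rownames(X) <- NULL
    list(data = MarkerMatrix(X, kind),
         labels = rownames(fixture@genotypes)[idx])
}

#' Add site-flip observation noise
#'
#' Independently flips every non-missing entry (0 to 1 or 1 to 0) with a
#' fixed error probability, emulating sequencing / bisulfite conversion
#' errors.
#'
#' @param x a \code{\linkS4class{MarkerMatrix}}.
#' @param p flip probability in [0, 1].
#' @return The noisy \code{MarkerMatrix}.
#' @export
addFlipNoise <- function(x, p) {
    stopifnot(is(x, "MarkerMatrix"), p >= 0, p <= 1)
    v <- x@values
    flip <- !is.na(v) & matrix(stats::runif(length(v)) < p, nrow(v), ncol(v))
    v[flip] <- 1 - v[flip]
    x@values <- v
    x
}
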