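## Readers and writers: delimited marker matrices, structured tree dumps
## (JSON; the canonical serialisation), Newick export and edge lists.

.toolHeader <- function(seed = NA) {
    sprintf("# cloneTree %s seed=%s",
            as.character(utils::packageVersion("cloneTree")),
            as.character(seed))
}

#' Read a binary marker matrix from delimited text
#'
#' Accepts comma- or tab-delimited files (auto-detected) with entries 0, 1
#' or NA, an optional header row of site names and optional leading comment
#' lines starting with \code{#}.
#'
#' @param path file path.
#' @param kind marker kind of the data.
#' @return A \code{\linkS4class{MarkerMatrix}}.
#' @export
readMarkerMatrix <- function(path, kind = c("methylation", "snv")) {
    kind <- match.arg(kind)
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    if (!length(lines)) stop("empty input file: ", path)
    sep <- if (grepl("\t", lines[1L])) "\t" else ","
    cells <- strsplit(lines, sep, fixed = TRUE)
    tok1 <- trimws(cells[[1L]])
    hasHeader <- !all(tok1 %in% c("0", "1", "NA", ""))
    siteNames <- if (hasHeader) tok1 else NULL
    rows <- cells[(1L + hasHeader):length(cells)]
    M <- length(rows[[1L]])
    v <- matrix(NA_real_, length(rows), M)
    for (i in seq_along(rows)) {
        tok <- trimws(rows[[i]])
        if (length(tok) != M)
            stop(sprintf("row %d has %d fields, expected %d", i,
                         length(tok), M))
        bad <- !(tok %in% c("0", "1", "NA"))
        if (any(bad))
            stop(sprintf("non-binary entry '%s' at row %d, column %d",
                         tok[which(bad)[1L]], i, which(bad)[1L]))
        v[i, ] <- suppressWarnings(as.numeric(tok))
    }
    if (!is.null(siteNames)) colnames(v) <- siteNames
    MarkerMatrix(v, kind)
}

#' Write a marker matrix as delimited text
#'
#' @param x a \code{\linkS4class{MarkerMatrix}}.
#' @param path output file.
#' @param seed seed recorded in the provenance header line.
#' @export
writeMarkerMatrix <- function(x, path, seed = NA) {
    v <- x@values
    if (is.null(colnames(v))) colnames(v) <- paste0("site", seq_len(ncol(v)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.toolHeader(seed), con)
    writeLines(paste(colnames(v), collapse = ","), con)
    writeLines(apply(v, 1L, function(r)
        paste(ifelse(is.na(r), "NA", format(r, trim = TRUE)),
              collapse = ",")), con)
    invisible(path)
}

## ---- structured tree dumps ----

#' Serialise / deserialise a tree
#'
#' The structured dump is the canonical tree serialisation: one record per
#' node with the label path, stick variables, parameter vector, branch
#' length, assigned-observation count and clone weight, plus the
#' hyperparameters. Newick export (see \code{\link{treeToNewick}}) cannot
#' carry the parameter vectors.
#'
#' @param tree a \code{\linkS4class{TssbTree}}.
#' @param path output (input) file.
#' @param seed seed recorded for provenance.
#' @return \code{writeTreeDump}: the path, invisibly; \code{readTreeDump}:
#'   a \code{TssbTree}.
#' @export
writeTreeDump <- function(tree, path, seed = NA) {
    pi <- cloneWeights(tree)
    recs <- lapply(names(tree@nodes), function(k) {
        n <- tree@nodes[[k]]
        list(path = I(n$path), nu = n$nu, psi = I(n$psi), theta = I(n$theta),
             branchLength = if (length(n$path)) n$t else NULL,
             assignedCount = length(n$assigned), pi = unname(pi[[k]]))
    })
    jsonlite::write_json(
        list(tool = .toolHeader(seed), hypers = tree@hypers, nodes = recs),
        path, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
}

#' @rdname writeTreeDump
#' @export
readTreeDump <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    nodes <- list()
    for (r in obj$nodes) {
        p <- as.integer(unlist(r$path))
        nodes[[labelKey(p)]] <- .newNode(
            p, nu = r$nu, psi = as.numeric(unlist(r$psi)),
            theta = as.numeric(unlist(r$theta)),
            t = if (length(p)) r$branchLength else NA_real_,
            assigned = seq_len(r$assignedCount))
    }
    new("TssbTree", nodes = nodes,
        hypers = lapply(obj$hypers, as.numeric))
}

#' Newick export of an instantiated tree
#'
#' Emits Newick with quoted internal/leaf labels of the form
#' \code{'label:count'} (clone path and assigned-observation count), branch
#' lengths equal to the per-node branch lengths, and an unlabeled root. A
#' root-only tree is emitted as \code{root;}.
#'
#' @param tree a \code{\linkS4class{TssbTree}}.
#' @return Newick string.
#' @export
treeToNewick <- function(tree) {
    nodes <- tree@nodes
    keys <- names(nodes)
    kids <- .childrenMap(keys)
    lab <- function(k) {
        sprintf("'%s:%d'", paste(nodes[[k]]$path, collapse = "."),
                length(nodes[[k]]$assigned))
    }
    rec <- function(k) {
        ch <- kids[[k]]
        body <- if (length(ch))
            paste0("(", paste(vapply(orderKeys(ch), rec, character(1)),
                              collapse = ","), ")")
        else ""
        paste0(body, lab(k), sprintf(":%.6f", nodes[[k]]$t))
    }
    ch <- kids[["0"]]
    if (!length(ch)) return("root;")
    paste0("(", paste(vapply(orderKeys(ch), rec, character(1)),
                      collapse = ","), ");")
}

#' Write all tree artifacts
#'
#' Writes the canonical structured dump (\code{<prefix>.json}), the Newick
#' form (\code{<prefix>.nwk}) and an edge-list CSV
#' (\code{<prefix>_edges.csv}) with per-node weight, depth and the
#' discretised genotype call at threshold \code{eta}.
#'
#' @param tree a \code{\linkS4class{TssbTree}}.
#' @param prefix output path prefix.
#' @param eta state-call threshold for the genotype column.
#' @param seed seed recorded for provenance.
#' @return Character vector of the files written, invisibly.
#' @export
writeTree <- function(tree, prefix, eta = 1, seed = NA) {
    files <- c(paste0(prefix, ".json"), paste0(prefix, ".nwk"),
               paste0(prefix, "_edges.csv"))
    writeTreeDump(tree, files[1L], seed = seed)
    writeLines(treeToNewick(tree), files[2L])
    pi <- cloneWeights(tree)
    keys <- names(tree@nodes)
    rows <- vapply(keys, function(k) {
        n <- tree@nodes[[k]]
        paste(c(if (k == "0") "" else parentKey(k), k,
                sprintf("%.6g", pi[[k]]), length(n$path),
                paste(ifelse(n$theta >= eta, 1L, 0L), collapse = ""),
                if (k == "0") "" else sprintf("%.6f", n$t)),
              collapse = ",")
    }, character(1))
    writeLines(c(.toolHeader(seed), "parent,node,pi,depth,genotype,t", rows),
               files[3L])
    invisible(files)
}

#' Serialise / deserialise a simulation fixture
#'
#' @param fixture a \code{\linkS4class{CloneFixture}}.
#' @param path file path.
#' @param seed seed recorded for provenance.
#' @export
writeFixtureDump <- function(fixture, path, seed = NA) {
    jsonlite::write_json(
        list(tool = .toolHeader(seed), mode = fixture@mode,
             clones = lapply(seq_along(fixture@labels), function(i)
                 list(path = I(fixture@labels[[i]]),
                      frequency = fixture@frequencies[i],
                      genotype = I(fixture@genotypes[i, ])))),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeFixtureDump
#' @export
readFixtureDump <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    labels <- lapply(obj$clones, function(cl) as.integer(unlist(cl$path)))
    geno <- do.call(rbind, lapply(obj$clones, function(cl)
        as.numeric(unlist(cl$genotype))))
    rownames(geno) <- vapply(labels, labelKey, character(1))
    new("CloneFixture", mode = obj$mode, labels = labels,
        frequencies = vapply(obj$clones, `[[`, numeric(1), "frequency"),
        genotypes = geno)
}
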