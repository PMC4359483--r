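#' Clone label utilities
#'
#' Clone labels address nodes of the infinite clone tree: a label is a finite
#' sequence of positive integers, the root being the empty sequence. The
#' depth of a clone is the length of its label, so the root has depth 0; the
#' parent of a non-root clone is obtained by dropping the last element of its
#' label.
#'
#' @param label integer vector (possibly empty) of positive integers.
#' @return \code{cloneDepth}: the depth (a nonnegative integer).
#' @examples
#' cloneDepth(c(1, 2))      # 2
#' parentLabel(c(1, 2))     # 1
#' cloneDepth(integer(0))   # 0 (root)
#' @export
cloneDepth <- function(label) {
    .checkLabel(label)
    length(label)
}

#' @rdname cloneDepth
#' @return \code{parentLabel}: the parent's label (an integer vector).
#' @export
parentLabel <- function(label) {
    .checkLabel(label)
    if (length(label) == 0L)
        stop("the root clone has no parent")
    label[-length(label)]
}

.checkLabel <- function(label) {
    if (length(label) && (any(label < 1) || any(label != floor(label))))
        stop("clone labels are sequences of positive integers")
    invisible(TRUE)
}

## Internal key scheme: root <-> "0", path c(1,2) <-> "0.1.2". A leading "0"
## keeps the root addressable as a list name and can never collide with a
## child index (children are numbered from 1).

labelKey <- function(path) paste(c(0L, path), collapse = ".")

keyToPath <- function(key) {
    p <- as.integer(strsplit(key, ".", fixed = TRUE)[[1L]])
    p[-1L]
}

parentKey <- function(key) {
    sub("\\.[0-9]+$", "", key)
}

keyDepth <- function(keys) {
    lengths(regmatches(keys, gregexpr(".", keys, fixed = TRUE)))
}

## order keys by depth, then lexicographically by numeric path components
orderKeys <- function(keys) {
    if (length(keys) <= 1L) return(keys)
    parts <- strsplit(keys, ".", fixed = TRUE)
    d <- lengths(parts)
    maxd <- max(d)
    pad <- vapply(parts, function(p)
        paste(formatC(as.integer(c(p, rep(0L, maxd - length(p)))),
                      width = 6, flag = "0"), collapse = "."), character(1))
    keys[order(d, pad)]
}
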