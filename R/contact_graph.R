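## Residue contact graphs at a distance cutoff.

#' Build the residue contact graph of a chain
#'
#' Two residues are in contact when their minimal inter-residue atom distance
#' (under the chosen atom mode) is at most `cutoff` Angstrom and their
#' sequence separation is at least `minSeqSep`.  The default mode measures
#' the minimum over all heavy-atom pairs; `"CA"` and `"CB"` use a single
#' representative atom per residue (glycine, which has no C-beta, falls back
#' to C-alpha with a warning).
#'
#' @param chain a [ChainStructure-class].
#' @param cutoff contact distance cutoff in Angstrom (default 5).
#' @param atomMode `"heavy"` (default), `"CA"` or `"CB"`.
#' @param minSeqSep minimal sequence separation |i - j| for a contact
#'   (default 1: sequence neighbours are allowed).
#' @return A [ResidueContactGraph-class].
#' @examples
#' ch <- makeStructure(12, geometry = "spiral", seed = 1)
#' g <- buildContactGraph(ch, cutoff = 5)
#' g
#' @export
buildContactGraph <- function(chain, cutoff = 5, atomMode = c("heavy", "CA", "CB"),
                              minSeqSep = 1L) {
    atomMode <- match.arg(atomMode)
    stopifnot(cutoff > 0)
    n <- nResidues(chain)
    atm <- chain@atoms
    if (atomMode %in% c("CA", "CB")) {
        sel <- atm[atm$name == atomMode, , drop = FALSE]
        missing <- setdiff(seq_len(n), sel$resIndex)
        if (length(missing)) {
            if (atomMode == "CB")
                warning("no CB atom for residue(s) ",
                        paste(missing, collapse = ","),
                        "; falling back to CA")
            else warning("no CA atom for residue(s) ",
                         paste(missing, collapse = ","),
                         "; using first atom")
            fallbackName <- if (atomMode == "CB") "CA" else NULL
            for (i in missing) {
                cand <- atm[atm$resIndex == i, , drop = FALSE]
                if (!is.null(fallbackName) && any(cand$name == fallbackName))
                    cand <- cand[cand$name == fallbackName, , drop = FALSE]
                sel <- rbind(sel, cand[1L, , drop = FALSE])
            }
        }
        sel <- sel[!duplicated(sel$resIndex), , drop = FALSE]
        atm <- sel
    }
    coords <- as.matrix(atm[, c("x", "y", "z")])
    resOf <- atm$resIndex
    D <- as.matrix(stats::dist(coords))
    ## minimal inter-residue distance per residue pair
    M <- matrix(Inf, n, n)
    for (i in seq_len(n)) {
        rows <- which(resOf == i)
        dmin <- if (length(rows) == 1L) D[rows, ] else
            apply(D[rows, , drop = FALSE], 2L, min)
        M[i, ] <- vapply(split(dmin, resOf), min, numeric(1))[as.character(seq_len(n))]
    }
    pairs <- which(upper.tri(M) & M <= cutoff, arr.ind = TRUE)
    if (nrow(pairs)) {
        keep <- (pairs[, 2L] - pairs[, 1L]) >= minSeqSep
        pairs <- pairs[keep, , drop = FALSE]
        pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    }
    edges <- matrix(as.integer(pairs), ncol = 2L,
                    dimnames = list(NULL, c("i", "j")))
    new("ResidueContactGraph", nNodes = as.integer(n), edges = edges,
        cutoff = as.numeric(cutoff), atomMode = atomMode,
        minSeqSep = as.integer(minSeqSep))
}

#' Construct a contact graph from an explicit edge list
#'
#' Mainly for tests and for re-importing exported edge lists.
#'
#' @param nNodes number of residues.
#' @param edges two-column matrix (or data.frame) of 1-based index pairs;
#'   order within a pair is irrelevant, duplicates are collapsed.
#' @param cutoff,atomMode,minSeqSep metadata carried on the object.
#' @return A [ResidueContactGraph-class].
#' @export
contactGraphFromEdges <- function(nNodes, edges, cutoff = 5,
                                  atomMode = "heavy", minSeqSep = 1L) {
    edges <- as.matrix(edges)
    if (nrow(edges)) {
        storage.mode(edges) <- "integer"
        edges <- t(apply(edges, 1L, sort))
        edges <- unique(edges)
        edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    } else edges <- matrix(integer(), ncol = 2L)
    colnames(edges) <- c("i", "j")
    new("ResidueContactGraph", nNodes = as.integer(nNodes), edges = edges,
        cutoff = as.numeric(cutoff), atomMode = atomMode,
        minSeqSep = as.integer(minSeqSep))
}

#' Neighbours of a residue in the contact graph
#'
#' @param g a [ResidueContactGraph-class].
#' @param i 1-based residue index.
#' @return sorted integer vector of contacting residue indices.
#' @export
contactNeighbors <- function(g, i) {
    if (length(i) != 1L || i < 1L || i > g@nNodes)
        stop("residue index out of range: ", i)
    e <- g@edges
    unname(sort(c(e[e[, 1L] == i, 2L], e[e[, 2L] == i, 1L])))
}

#' Dense adjacency matrix of a contact graph
#'
#' @param g a [ResidueContactGraph-class].
#' @return symmetric 0/1 integer matrix with zero diagonal.
#' @export
adjacencyMatrix <- function(g) {
    A <- matrix(0L, g@nNodes, g@nNodes)
    e <- g@edges
    if (nrow(e)) {
        A[e] <- 1L
        A[e[, c(2L, 1L), drop = FALSE]] <- 1L
    }
    A
}

#' Edge list of a contact graph
#' @param g a [ResidueContactGraph-class].
#' @return two-column integer matrix (i < j).
#' @export
contactEdges <- function(g) g@edges

#' Export / import contact maps
#'
#' `writeEdgeList` writes the contacts as a two-column TSV (with header);
#' `readEdgeList` reads it back (the node count is `max(index)` unless
#' given).  `writeContactMatrix` writes the dense 0/1 adjacency matrix as
#' CSV; `readContactMatrix` is its counterpart.
#'
#' @param g a [ResidueContactGraph-class].
#' @param path file path.
#' @param nNodes optional node count when reading an edge list.
#' @return the graph (readers) or `path` invisibly (writers).
#' @export
writeEdgeList <- function(g, path) {
    utils::write.table(g@edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path, nNodes = NULL) {
    e <- utils::read.table(path, header = TRUE, sep = "\t")
    if (is.null(nNodes)) nNodes <- if (nrow(e)) max(e) else 1L
    contactGraphFromEdges(nNodes, e)
}

#' @rdname writeEdgeList
#' @export
writeContactMatrix <- function(g, path) {
    utils::write.table(adjacencyMatrix(g), path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
readContactMatrix <- function(path) {
    A <- as.matrix(utils::read.table(path, sep = ","))
    dimnames(A) <- NULL
    if (nrow(A) != ncol(A) || any(A != t(A)))
        stop("contact matrix must be square and symmetric")
    contactGraphFromEdges(nrow(A), which(A == 1 & upper.tri(A), arr.ind = TRUE))
}
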