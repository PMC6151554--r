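## Contact-graph centrality descriptors.
##
## All distances are hop counts on the unweighted contact graph.  Measures
## for a node are computed within its connected component; isolated nodes
## score 0 on every measure, and the "inverted" variants return 0 (not Inf)
## when the base measure is 0, so downstream feature tables stay finite.

## Adjacency list helper.
adjList <- function(g) {
    n <- g@nNodes
    adj <- vector("list", n)
    e <- g@edges
    for (k in seq_len(nrow(e))) {
        i <- e[k, 1L]; j <- e[k, 2L]
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
    }
    lapply(adj, sort)
}

#' Single-source shortest-path hop distances
#'
#' Breadth-first search from `source` over the unit-weight contact graph.
#' Unreachable nodes are absent from the result.
#'
#' @param g a [ResidueContactGraph-class].
#' @param source 1-based node index.
#' @return named integer vector of hop distances, names = reachable node
#'   indices (the source itself at distance 0).
#' @export
shortestPathLengths <- function(g, source) {
    if (source < 1L || source > g@nNodes)
        stop("node index out of range: ", source)
    adj <- adjList(g)
    dist <- rep(NA_integer_, g@nNodes)
    dist[source] <- 0L
    frontier <- source
    while (length(frontier)) {
        nxt <- integer()
        for (u in frontier) {
            for (v in adj[[u]]) {
                if (is.na(dist[v])) {
                    dist[v] <- dist[u] + 1L
                    nxt <- c(nxt, v)
                }
            }
        }
        frontier <- nxt
    }
    reach <- which(!is.na(dist))
    stats::setNames(dist[reach], reach)
}

#' All-pairs hop-distance matrix
#'
#' @param g a [ResidueContactGraph-class].
#' @return n x n numeric matrix of hop distances, `Inf` for unreachable
#'   pairs, 0 on the diagonal.
#' @export
allPairsDistances <- function(g) {
    n <- g@nNodes
    D <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
        d <- shortestPathLengths(g, s)
        D[s, as.integer(names(d))] <- d
    }
    D
}

#' Per-node centrality measures
#'
#' Individual descriptors of the contact-graph centrality set; see
#' [centralityProfile()] for the full 11-column profile.
#'
#' `graphEccentricity` is the longest shortest distance from a node to any
#' node of its component (0 for isolated nodes).  `sphereDegree` is the sum
#' of the degrees of a node's neighbours (the degree "at a second level");
#' its accumulated variant (SNN) additionally counts the node's own
#' neighbours, i.e. `degree + sphereDegree`.  `meanDistance` is the average
#' hop distance to the other reachable nodes and `closenessCentrality` the
#' reciprocal of their sum, so `closeness = 1 / (meanDistance * count)`.
#' The clustering coefficient divides the number of ordered adjacent pairs
#' among a node's `n` neighbours (`o`, twice the undirected edge count) by
#' the expected `n * (n - 1)`.
#'
#' @param g a [ResidueContactGraph-class].
#' @param i 1-based node index.
#' @param D optional precomputed [allPairsDistances()] matrix.
#' @return numeric(1) (integer for degree-type counts).
#' @name centralities
NULL

#' @rdname centralities
#' @export
graphEccentricity <- function(g, i, D = NULL) {
    if (is.null(D)) {
        d <- shortestPathLengths(g, i)
    } else {
        d <- D[i, is.finite(D[i, ])]
    }
    if (length(d) <= 1L) return(0)
    max(d)
}

#' @rdname centralities
#' @export
degreeCentrality <- function(g, i) length(contactNeighbors(g, i))

#' @rdname centralities
#' @export
sphereDegree <- function(g, i) {
    nb <- contactNeighbors(g, i)
    if (!length(nb)) return(0L)
    sum(vapply(nb, function(k) degreeCentrality(g, k), integer(1)))
}

#' @rdname centralities
#' @export
sphereDegreeAccumulated <- function(g, i)
    degreeCentrality(g, i) + sphereDegree(g, i)

#' @rdname centralities
#' @export
meanDistance <- function(g, i, D = NULL) {
    d <- if (is.null(D)) shortestPathLengths(g, i) else
        stats::setNames(D[i, is.finite(D[i, ])], which(is.finite(D[i, ])))
    d <- d[names(d) != as.character(i)]
    if (!length(d)) return(0)
    sum(d) / length(d)
}

#' @rdname centralities
#' @export
closenessCentrality <- function(g, i, D = NULL) {
    d <- if (is.null(D)) shortestPathLengths(g, i) else
        stats::setNames(D[i, is.finite(D[i, ])], which(is.finite(D[i, ])))
    d <- d[names(d) != as.character(i)]
    if (!length(d)) return(0)
    1 / sum(d)
}

#' @rdname centralities
#' @export
clusteringCoefficient <- function(g, i) {
    nb <- contactNeighbors(g, i)
    n <- length(nb)
    if (n <= 1L) return(0)
    A <- adjacencyMatrix(g)
    o <- sum(A[nb, nb])          # ordered adjacent pairs among neighbours
    o / (n * (n - 1))
}

## 1/x with the 0 -> 0 convention used for all inverted descriptors.
invertOrZero <- function(x) ifelse(x > 0, 1 / x, 0)

#' Traversity: single-shortest-path node usage counts
#'
#' For every unordered pair of residues in the same component, one shortest
#' path is selected deterministically and every node strictly interior to it
#' is credited once.  The two variants differ only in the tie-break among
#' equally short paths: with the pair oriented from its lower to its higher
#' residue index, variant `"A"` follows the lexicographically smallest
#' shortest path (always stepping to the smallest-index admissible
#' neighbour) and variant `"B"` the lexicographically largest (largest-index
#' neighbour).
#'
#' @param g a [ResidueContactGraph-class].
#' @param variant `"A"` or `"B"`.
#' @param D optional precomputed [allPairsDistances()] matrix.
#' @return integer vector of per-node traversal counts.
#' @export
traversity <- function(g, variant = c("A", "B"), D = NULL) {
    variant <- match.arg(variant)
    n <- g@nNodes
    if (is.null(D)) D <- allPairsDistances(g)
    adj <- adjList(g)
    counts <- integer(n)
    pick <- if (variant == "A") min else max
    for (s in seq_len(n - 1L)) {
        for (t in seq.int(s + 1L, n)) {
            if (!is.finite(D[s, t]) || D[s, t] < 2) next
            cur <- s
            while (cur != t) {
                cand <- adj[[cur]][D[adj[[cur]], t] == D[cur, t] - 1]
                cur <- pick(cand)
                if (cur != t) counts[cur] <- counts[cur] + 1L
            }
        }
    }
    counts
}

#' Full centrality profile of a contact graph
#'
#' Computes all 11 centrality descriptors for every residue: eccentricity
#' and its inverse, degree, sphere degree and its accumulated variant (SNN),
#' mean distance, closeness, clustering coefficient and its inverse, and the
#' two traversity variants.
#'
#' @param g a [ResidueContactGraph-class].
#' @return data.frame with one row per residue and the 11 descriptor
#'   columns, in this fixed order: `excentricity`, `excentricity_inverted`,
#'   `degree`, `sphere_degree`, `sphere_degree_accumulated`,
#'   `mean_distance`, `closeness`, `clustering_coefficient`,
#'   `clustering_coefficient_inverted`, `traversity_A`, `traversity_B`.
#' @examples
#' g <- contactGraphFromEdges(3, rbind(c(1, 2), c(2, 3)))
#' centralityProfile(g)
#' @export
centralityProfile <- function(g) {
    n <- g@nNodes
    D <- allPairsDistances(g)
    ecc <- vapply(seq_len(n), function(i) graphEccentricity(g, i, D), numeric(1))
    deg <- vapply(seq_len(n), function(i) degreeCentrality(g, i), integer(1))
    sph <- vapply(seq_len(n), function(i) as.integer(sphereDegree(g, i)), integer(1))
    md  <- vapply(seq_len(n), function(i) meanDistance(g, i, D), numeric(1))
    cls <- vapply(seq_len(n), function(i) closenessCentrality(g, i, D), numeric(1))
    cc  <- vapply(seq_len(n), function(i) clusteringCoefficient(g, i), numeric(1))
    data.frame(
        excentricity = ecc,
        excentricity_inverted = invertOrZero(ecc),
        degree = deg,
        sphere_degree = sph,
        sphere_degree_accumulated = deg + sph,
        mean_distance = md,
        closeness = cls,
        clustering_coefficient = cc,
        clustering_coefficient_inverted = invertOrZero(cc),
        traversity_A = traversity(g, "A", D),
        traversity_B = traversity(g, "B", D))
}
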