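# Brute-force oracles, independent of the package's graph code: dense
# adjacency matrices, Floyd-Warshall distances, explicit triangle counting
# and exhaustive shortest-path enumeration.

# Random undirected graph as a 0/1 adjacency matrix.
randomAdjacency <- function(n, p) {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.integer(runif(length(up)) < p)
    A + t(A)
}

graphFromAdjacency <- function(A) {
    contactGraphFromEdges(nrow(A), which(A == 1 & upper.tri(A), arr.ind = TRUE))
}

# All-pairs hop distances by Floyd-Warshall dynamic programming.
fwDistances <- function(A) {
    n <- nrow(A)
    D <- matrix(Inf, n, n)
    diag(D) <- 0
    D[A == 1] <- 1
    for (k in seq_len(n))
        for (i in seq_len(n))
            D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    D
}

# Every shortest path from s to t as a list of index vectors.
allShortestPaths <- function(A, D, s, t) {
    rec <- function(cur) {
        if (cur == t) return(list(t))
        nbrs <- which(A[cur, ] == 1 & D[, t] == D[cur, t] - 1)
        out <- list()
        for (v in nbrs)
            for (p in rec(v)) out <- c(out, list(c(cur, p)))
        out
    }
    rec(s)
}

# Traversity by exhaustive path enumeration: for each unordered pair, list
# every shortest path, order them lexicographically by the index sequence
# (pairs oriented from the lower-index endpoint), pick the first (variant A)
# or last (variant B) and credit its interior nodes.
oracleTraversity <- function(A, variant) {
    D <- fwDistances(A)
    n <- nrow(A)
    counts <- integer(n)
    for (s in seq_len(n - 1L)) for (t in seq.int(s + 1L, n)) {
        if (!is.finite(D[s, t]) || D[s, t] < 2) next
        paths <- allShortestPaths(A, D, s, t)
        mat <- do.call(rbind, paths)
        ord <- do.call(order, as.data.frame(mat))
        chosen <- paths[[if (variant == "A") ord[1L] else ord[length(ord)]]]
        interior <- chosen[-c(1L, length(chosen))]
        counts[interior] <- counts[interior] + 1L
    }
    counts
}

# Full 11-measure profile computed only from the adjacency matrix.
oracleProfile <- function(A) {
    n <- nrow(A)
    D <- fwDistances(A)
    deg <- rowSums(A)
    ecc <- vapply(seq_len(n), function(i) {
        d <- D[i, is.finite(D[i, ])]
        d <- d[-match(0, d)]
        if (!length(d)) 0 else max(d)
    }, numeric(1))
    sph <- as.vector(A %*% deg)
    sums <- vapply(seq_len(n), function(i) {
        d <- D[i, ]
        sum(d[is.finite(d) & seq_len(n) != i])
    }, numeric(1))
    cnt <- vapply(seq_len(n), function(i)
        sum(is.finite(D[i, ]) & seq_len(n) != i), numeric(1))
    tri <- diag(A %*% A %*% A) / 2          # triangles through each node
    cc <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
    data.frame(
        excentricity = ecc,
        excentricity_inverted = ifelse(ecc > 0, 1 / ecc, 0),
        degree = deg,
        sphere_degree = sph,
        sphere_degree_accumulated = deg + sph,
        mean_distance = ifelse(cnt > 0, sums / cnt, 0),
        closeness = ifelse(sums > 0, 1 / sums, 0),
        clustering_coefficient = cc,
        clustering_coefficient_inverted = ifelse(cc > 0, 1 / cc, 0),
        traversity_A = oracleTraversity(A, "A"),
        traversity_B = oracleTraversity(A, "B"))
}

# Chain fixture with several heavy atoms per residue, for all-atom contact
# oracles.
makeMultiAtomChain <- function(n, seed = 1) {
    set.seed(seed)
    centers <- matrix(0, n, 3)
    for (k in seq.int(2, n)) {
        v <- rnorm(3)
        centers[k, ] <- centers[k - 1, ] + 3.8 * v / sqrt(sum(v^2))
    }
    nAtoms <- sample(1:4, n, replace = TRUE)
    atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
        offs <- matrix(rnorm(3 * nAtoms[i], sd = 0.8), ncol = 3)
        offs[1, ] <- 0
        data.frame(resIndex = i,
                   name = c("CA", "CB", "CG", "CD")[seq_len(nAtoms[i])],
                   elem = "C",
                   x = centers[i, 1] + offs[, 1],
                   y = centers[i, 2] + offs[, 2],
                   z = centers[i, 3] + offs[, 3])
    }))
    residues <- data.frame(seqIndex = seq_len(n), resno = seq_len(n),
                           insert = "", aa = sample(c("A", "L", "G", "K"), n,
                                                    replace = TRUE))
    new("ChainStructure", pdbID = "multi", chainID = "A",
        residues = residues, atoms = atoms)
}

# Exhaustive all-atom-pair contact scan.
oracleContactEdges <- function(chain, cutoff, minSeqSep = 1) {
    atm <- chain@atoms
    n <- nrow(chain@residues)
    edges <- NULL
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
        if (j - i < minSeqSep) next
        ai <- atm[atm$resIndex == i, c("x", "y", "z")]
        aj <- atm[atm$resIndex == j, c("x", "y", "z")]
        dmin <- Inf
        for (a in seq_len(nrow(ai))) for (b in seq_len(nrow(aj)))
            dmin <- min(dmin, sqrt(sum((ai[a, ] - aj[b, ])^2)))
        if (dmin <= cutoff) edges <- rbind(edges, c(i, j))
    }
    if (is.null(edges)) matrix(integer(), ncol = 2) else edges
}
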