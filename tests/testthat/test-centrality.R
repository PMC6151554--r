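pathGraph <- function(n) contactGraphFromEdges(n, cbind(1:(n - 1), 2:n))
completeGraph <- function(n) contactGraphFromEdges(n, t(combn(n, 2)))
cycleGraph <- function(n) contactGraphFromEdges(n, rbind(cbind(1:(n - 1), 2:n),
                                                         c(1, n)))

test_that("shortest-path lengths match the dynamic-programming oracle", {
    p4 <- pathGraph(4)
    expect_equal(shortestPathLengths(p4, 1),
                 c(`1` = 0L, `2` = 1L, `3` = 2L, `4` = 3L))
    disc <- contactGraphFromEdges(4, rbind(c(1, 2), c(3, 4)))
    expect_equal(sort(as.integer(names(shortestPathLengths(disc, 1)))), 1:2)
    set.seed(21)
    A <- randomAdjacency(15, 0.25)
    D <- fwDistances(A)
    g <- graphFromAdjacency(A)
    for (s in 1:15) {
        d <- shortestPathLengths(g, s)
        expect_equal(as.integer(names(d)), which(is.finite(D[s, ])))
        expect_equal(unname(d), unname(D[s, is.finite(D[s, ])]))
    }
})

test_that("named graphs give the textbook centrality values", {
    p3 <- centralityProfile(pathGraph(3))
    expect_equal(p3$excentricity, c(2, 1, 2))
    expect_equal(p3$degree, c(1L, 2L, 1L))
    expect_equal(p3$sphere_degree, c(2L, 2L, 2L))
    expect_equal(p3$sphere_degree_accumulated, c(3L, 4L, 3L))
    expect_equal(p3$mean_distance[2], 1)
    expect_equal(p3$closeness[2], 0.5)
    expect_equal(p3$clustering_coefficient, c(0, 0, 0))
    expect_equal(p3$traversity_A, c(0L, 1L, 0L))
    expect_equal(p3$traversity_B, c(0L, 1L, 0L))
    k4 <- centralityProfile(completeGraph(4))
    expect_equal(k4$degree, rep(3L, 4))
    expect_equal(k4$excentricity, rep(1, 4))
    expect_equal(k4$mean_distance, rep(1, 4))
    expect_equal(k4$closeness, rep(1 / 3, 4))
    expect_equal(k4$clustering_coefficient, rep(1, 4))   # n=3, o=6
    expect_equal(k4$traversity_A, rep(0L, 4))
    k5 <- centralityProfile(completeGraph(5))
    expect_equal(k5$excentricity_inverted, rep(1, 5))
})

test_that("isolated nodes score zero everywhere and inverses stay finite", {
    g <- contactGraphFromEdges(4, rbind(c(1, 2), c(2, 3)))
    prof <- centralityProfile(g)
    expect_equal(unlist(prof[4, ]), setNames(rep(0, 11), names(prof)))
    expect_true(all(is.finite(as.matrix(prof))))
})

test_that("profiles match the brute-force oracle on random graphs", {
    set.seed(33)
    for (rep in 1:20) {
        n <- sample(5:15, 1)
        A <- randomAdjacency(n, runif(1, 0.15, 0.6))
        got <- centralityProfile(graphFromAdjacency(A))
        expect_equal(got, oracleProfile(A), tolerance = 1e-12,
                     ignore_attr = TRUE)
    }
})

test_that("eccentricity and closeness identities hold per component", {
    set.seed(17)
    for (rep in 1:10) {
        n <- sample(6:14, 1)
        A <- randomAdjacency(n, 0.3)
        g <- graphFromAdjacency(A)
        prof <- centralityProfile(g)
        D <- fwDistances(A)
        for (i in seq_len(n)) {
            reach <- which(is.finite(D[i, ]) & seq_len(n) != i)
            if (!length(reach)) next
            expect_equal(prof$excentricity_inverted[i] * prof$excentricity[i], 1)
            expect_equal(prof$closeness[i] * sum(D[i, reach]), 1)
            expect_equal(prof$mean_distance[i] * length(reach), sum(D[i, reach]))
            expect_equal(prof$closeness[i],
                         1 / (prof$mean_distance[i] * length(reach)))
        }
    }
})

test_that("vertex-transitive graphs with unique shortest paths have constant centralities", {
    ## odd cycles and complete graphs: every shortest path is unique, so
    ## even the single-path traversity must be symmetric
    for (g in list(cycleGraph(5), cycleGraph(7), completeGraph(5))) {
        prof <- centralityProfile(g)
        for (cl in names(prof))
            expect_equal(length(unique(prof[[cl]])), 1L, label = cl)
    }
})

test_that("the two traversity variants split tied paths as documented", {
    c4 <- cycleGraph(4)   # edges 1-2, 2-3, 3-4, 1-4
    expect_equal(traversity(c4, "A"), c(1L, 1L, 0L, 0L))
    expect_equal(traversity(c4, "B"), c(0L, 0L, 1L, 1L))
    ## one interior credit per distance-2 pair in both variants
    expect_equal(sum(traversity(c4, "A")), 2L)
    expect_equal(sum(traversity(c4, "B")), 2L)
})

test_that("traversity totals count interior slots of single selected paths", {
    set.seed(8)
    for (rep in 1:8) {
        n <- sample(5:10, 1)
        A <- randomAdjacency(n, 0.35)
        g <- graphFromAdjacency(A)
        D <- fwDistances(A)
        interiorSlots <- 0
        for (s in seq_len(n - 1)) for (t in seq.int(s + 1, n))
            if (is.finite(D[s, t]) && D[s, t] >= 2)
                interiorSlots <- interiorSlots + D[s, t] - 1
        expect_equal(sum(traversity(g, "A")), interiorSlots)
        expect_equal(sum(traversity(g, "B")), interiorSlots)
    }
})
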