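test_that("initial chromosomes have sizes uniform on [1, m/10]", {
    set.seed(1)
    ctrl <- gaControl(populationSize = 50L)
    pop <- initPopulation(100, ctrl)
    expect_length(pop, 50L)
    expect_true(all(lengths(pop) >= 1 & lengths(pop) <= 10))
    expect_true(all(vapply(pop, anyDuplicated, integer(1)) == 0))
    ## reproducibility under a fixed seed
    set.seed(9); a <- initPopulation(100, ctrl)
    set.seed(9); b <- initPopulation(100, ctrl)
    expect_identical(a, b)
    ## size histogram consistent with uniform over 1..10 (chi-square)
    set.seed(2)
    big <- gaControl(populationSize = 10000L)
    sizes <- lengths(initPopulation(100, big))
    p <- chisq.test(tabulate(sizes, 10), p = rep(0.1, 10))$p.value
    expect_gt(p, 1e-3)
    ## clamping below 10 descriptors
    expect_warning(popSmall <- initPopulation(5, ctrl), "clamp")
    expect_true(all(lengths(popSmall) == 1))
})

test_that("binary tournament prefers fitness, then smaller subsets", {
    pop <- list(c(1L, 2L), c(3L, 4L, 5L))
    set.seed(3)
    wins <- replicate(4000, length(tournamentSelect(pop, c(0.9, 0.1))) == 2L)
    expect_gt(mean(wins), 0.70)          # exact draw enumeration gives 0.75
    expect_lt(mean(wins), 0.80)
    ## equal fitness: the larger subset only survives an all-larger draw (p=.25)
    set.seed(4)
    big <- replicate(4000, length(tournamentSelect(pop, c(0.5, 0.5))) == 3L)
    expect_gt(mean(big), 0.20); expect_lt(mean(big), 0.30)
    expect_equal(tournamentSelect(list(c(7L)), 0.2), 7L)
})

test_that("SSOCF crossover preserves sizes and common features", {
    expect_equal(ssocfCrossover(c(1L, 2L, 3L), c(1L, 2L, 3L)),
                 list(1:3, 1:3))
    set.seed(5)
    for (rep in 1:50) {
        ch <- ssocfCrossover(c(1L, 2L), c(1L, 3L))
        expect_true(identical(ch, list(c(1L, 2L), c(1L, 3L))) ||
                    identical(ch, list(c(1L, 3L), c(1L, 2L))))
    }
    set.seed(6)
    for (rep in 1:1000) {
        m <- 30L
        p1 <- sort(sample(m, sample(1:10, 1)))
        p2 <- sort(sample(m, sample(1:10, 1)))
        ch <- ssocfCrossover(p1, p2)
        expect_equal(length(ch[[1]]), length(p1))
        expect_equal(length(ch[[2]]), length(p2))
        common <- intersect(p1, p2)
        expect_true(all(common %in% ch[[1]]) && all(common %in% ch[[2]]))
        expect_equal(sort(union(ch[[1]], ch[[2]])), sort(union(p1, p2)))
    }
})

test_that("toggle mutation adds or removes one index and never empties", {
    set.seed(7)
    for (rep in 1:200) {
        chrom <- sort(sample(20L, sample(1:5, 1)))
        mut <- mutateChromosome(chrom, 20L, prob = 1)
        diff <- union(setdiff(mut, chrom), setdiff(chrom, mut))
        expect_length(diff, 1L)
        expect_gte(length(mut), 1L)
    }
    ## the guarded removal: singleton chromosome can only grow
    set.seed(8)
    for (rep in 1:50)
        expect_length(mutateChromosome(5L, 20L, prob = 1), 2L)
    ## prob = 0 is the identity
    expect_identical(mutateChromosome(c(1L, 4L), 20L, prob = 0), c(1L, 4L))
})

test_that("fitness is perfect on separable data and near zero under label permutation", {
    ft <- makeFeatureTable(nInstances = 200, nInformative = 3, nNoise = 5,
                           effectSize = 3, seed = 11)
    ctrl <- gaControl()
    set.seed(12)
    rec <- chromosomeFitness(1:3, ft, ctrl)
    expect_gte(rec$mcc, 0.95)
    expect_equal(rec$size, 3L)
    set.seed(13)
    yPerm <- sample(classLabels(ft))
    ftPerm <- FeatureTable(featureValues(ft), yPerm)
    recPerm <- chromosomeFitness(1:3, ftPerm, ctrl)
    expect_lt(abs(recPerm$mcc), 0.15)
})

test_that("class weights trade majority accuracy for minority recall", {
    ft <- makeFeatureTable(nInstances = 250, nInformative = 2, nNoise = 3,
                           classBalance = 0.15, effectSize = 1.2, seed = 14)
    x <- featureValues(ft)[, 1:2]; y <- classLabels(ft)
    recallOf <- function(w) {
        fit <- trainClassifier(classifierSpec(classWeights = w), x, y)
        pred <- predictClassifier(fit, x)$labels
        sum(pred == "critical" & y == "critical") / sum(y == "critical")
    }
    rWeighted <- recallOf(c(critical = 9, "non-critical" = 3))
    rFlat <- recallOf(c(critical = 1, "non-critical" = 1))
    expect_gte(rWeighted, rFlat)
})

test_that("evolution is elitist-monotone and reproducible under a seed", {
    ft <- makeFeatureTable(nInstances = 80, nInformative = 2, nNoise = 10,
                           classBalance = 0.3, seed = 15)
    ctrl <- gaControl(maxGenerations = 6L, populationSize = 20L)
    selA <- gaSelect(ft, ctrl, seed = 21)
    selB <- gaSelect(ft, ctrl, seed = 21)
    expect_identical(selA$best$chromosome, selB$best$chromosome)
    expect_identical(selA$history, selB$history)
    expect_true(all(diff(selA$history$bestMCC) >= 0))
    json <- withr::local_tempfile(fileext = ".json")
    writeGAReport(selA, json)
    rep <- jsonlite::fromJSON(json)
    expect_equal(rep$selected, selA$best$names)
    expect_equal(rep$bestMCC, selA$best$mcc)
})
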