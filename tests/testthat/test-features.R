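smallTable <- function() {
    x <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(2, 2, 2, 2))
    FeatureTable(x, factor(c("critical", "non-critical", "critical",
                             "non-critical")))
}

test_that("CSV and ARFF round-trips preserve values and classes", {
    ft <- makeFeatureTable(nInstances = 30, nInformative = 2, nNoise = 2,
                           seed = 2)
    csv <- withr::local_tempfile(fileext = ".csv")
    writeFeatureTable(ft, csv)
    back <- readFeatureTable(csv)
    expect_equal(featureValues(back), featureValues(ft), tolerance = 1e-12)
    expect_equal(as.character(classLabels(back)), as.character(classLabels(ft)))
    arff <- withr::local_tempfile(fileext = ".arff")
    writeFeatureTable(ft, arff)
    back2 <- readFeatureTable(arff)
    expect_equal(unname(featureValues(back2)), unname(featureValues(ft)),
                 tolerance = 1e-12)
    expect_equal(levels(classLabels(back2)), c("critical", "non_critical"))
    ## numeric (regression) class survives both formats
    ftn <- FeatureTable(featureValues(ft), runif(30))
    writeFeatureTable(ftn, arff)
    expect_true(is.numeric(classLabels(readFeatureTable(arff))))
})

test_that("malformed feature files are rejected", {
    csv <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("a,b,class", "1,x,critical", "2,y,non-critical"), csv)
    expect_error(readFeatureTable(csv), "non-numeric")
    writeLines(c("a,b", "1,2"), csv)
    expect_error(readFeatureTable(csv), "class column")
    writeLines(c("a,class", ",critical", "2,non-critical"), csv)
    expect_error(readFeatureTable(csv), "missing")
})

test_that("remove-useless drops exactly the constant descriptors", {
    ft <- smallTable()
    out <- removeUseless(ft)
    expect_equal(descriptorNames(out), c("a", "b"))
    expect_equal(filterLog(out)[[1]]$removed, "c")
    allVary <- FeatureTable(cbind(a = 1:4, b = c(2, 1, 4, 3)),
                            classLabels(ft))
    expect_equal(descriptorNames(removeUseless(allVary)), c("a", "b"))
    ## fixture with 10 constants among 50
    set.seed(3)
    x <- matrix(rnorm(40 * 50), 40, 50,
                dimnames = list(NULL, sprintf("d%02d", 1:50)))
    const <- sample(50, 10)
    x[, const] <- rep(seq_len(10), each = 40)
    ftBig <- FeatureTable(x, factor(rep(c("critical", "non-critical"), 20)))
    outBig <- removeUseless(ftBig)
    expect_equal(sort(filterLog(outBig)[[1]]$removed),
                 sort(colnames(x)[const]))
    ## idempotence
    expect_equal(featureValues(removeUseless(outBig)), featureValues(outBig))
})

test_that("the Spearman filter removes duplicates and monotone transforms, keep-first", {
    set.seed(4)
    base <- rnorm(50)
    x <- cbind(a = base, b = rnorm(50), a_copy = base,
               a_mono = exp(3 * base) + 5, c = rnorm(50))
    ft <- FeatureTable(x, factor(rep(c("critical", "non-critical"), 25)))
    out <- spearmanRedundancyFilter(ft)
    expect_equal(descriptorNames(out), c("a", "b", "c"))
    expect_equal(sort(filterLog(out)[[1]]$removed), c("a_copy", "a_mono"))
    ## row-order invariance and idempotence
    perm <- sample(50)
    ftPerm <- FeatureTable(x[perm, ], classLabels(ft)[perm])
    expect_equal(descriptorNames(spearmanRedundancyFilter(ftPerm)),
                 descriptorNames(out))
    expect_equal(descriptorNames(spearmanRedundancyFilter(out)),
                 descriptorNames(out))
    ## planted twins from the generator are exactly the columns dropped
    ftTw <- makeFeatureTable(nInstances = 500, nInformative = 3, nNoise = 14,
                             nTwins = 3, seed = 5)
    rho <- abs(cor(featureValues(ftTw)[, attr(ftTw, "twins")[1]],
                   featureValues(ftTw)[, "inf01"], method = "spearman"))
    expect_gte(rho, 0.99)
    outTw <- spearmanRedundancyFilter(ftTw)
    expect_equal(sort(filterLog(outTw)[[1]]$removed), sort(attr(ftTw, "twins")))
    ## constant columns flag a warning but do not crash
    ftC <- smallTable()
    expect_warning(spearmanRedundancyFilter(ftC), "constant")
})

test_that("MDL discretization accepts real splits and rejects noise", {
    set.seed(6)
    y <- factor(rep(c("critical", "non-critical"), each = 100))
    sep <- c(rnorm(100, 3), rnorm(100, 0))
    expect_gt(length(mdlDiscretize(sep, y)), 0)
    expect_equal(length(mdlDiscretize(rnorm(200), y)), 0)
    ## a descriptor identical to the class keeps the full class entropy
    bin <- as.numeric(y == "critical")
    expect_equal(informationGain(bin, y), 1)    # balanced classes: H = 1 bit
    expect_equal(informationGain(rnorm(200), y), 0)
})

test_that("the information-gain filter keeps planted signal and drops noise", {
    ft <- makeFeatureTable(nInstances = 200, nInformative = 4, nNoise = 40,
                           seed = 7)
    out <- informationGainFilter(ft)
    expect_true(all(attr(ft, "informative") %in% descriptorNames(out)))
    noiseKept <- sum(grepl("^noise", descriptorNames(out)))
    expect_lte(noiseKept, 4)                    # >= 90% of 40 dropped
    ## numeric targets are rejected with guidance
    ftn <- FeatureTable(featureValues(ft), runif(200))
    expect_error(informationGainFilter(ftn), "binary class")
})

test_that("the filter cascade runs in fixed order with full provenance", {
    ft <- makeFeatureTable(nInstances = 150, nInformative = 3, nNoise = 20,
                           nTwins = 2, seed = 8)
    x <- cbind(featureValues(ft), const = 1)
    ft2 <- FeatureTable(x, classLabels(ft))
    out <- filterFeatures(ft2)
    lg <- filterLog(out)
    expect_equal(vapply(lg, `[[`, "", "filter"),
                 c("remove_useless", "spearman_redundancy", "information_gain"))
    expect_equal(lg[[1]]$removed, "const")
    expect_true(all(attr(ft, "twins") %in% lg[[2]]$removed))
    json <- withr::local_tempfile(fileext = ".json")
    writeFilterReport(out, json)
    expect_equal(jsonlite::fromJSON(json)$filter[1], "remove_useless")
})
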