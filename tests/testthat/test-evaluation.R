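labelled <- function(tp, fn, fp, tn) {
    truth <- factor(rep(c("critical", "critical", "non-critical", "non-critical"),
                        c(tp, fn, fp, tn)),
                    levels = c("critical", "non-critical"))
    pred <- factor(rep(c("critical", "non-critical", "critical", "non-critical"),
                       c(tp, fn, fp, tn)),
                   levels = c("critical", "non-critical"))
    list(truth = truth, pred = pred)
}

test_that("confusion metrics reproduce closed-form values", {
    ## perfect prediction
    d <- labelled(30, 0, 0, 70)
    perfect <- confusionMetrics(d$truth, d$truth, scores = ifelse(d$truth == "critical", 1, -1))
    expect_equal(unname(perfect$weighted[c("tpRate", "fpRate", "precision",
                                           "recall", "mcc", "rocArea")]),
                 c(1, 0, 1, 1, 1, 1))
    ## all-majority prediction on an 80/20 split
    d <- labelled(0, 20, 0, 80)
    maj <- confusionMetrics(d$truth, d$pred)
    expect_equal(unname(maj$weighted["tpRate"]), 0.8)
    expect_equal(unname(maj$weighted["mcc"]), 0)
    ## fixed confusion matrix against the MCC formula by hand:
    ## TP=40 FN=10 FP=20 TN=130 -> marginals 60, 50, 150, 140
    d <- labelled(40, 10, 20, 130)
    rep <- confusionMetrics(d$truth, d$pred)
    expect_equal(unname(rep$perClass$mcc[1]),
                 (40 * 130 - 20 * 10) / sqrt(60 * 50 * 150 * 140),
                 tolerance = 1e-12)
    crit <- rep$perClass[rep$perClass$class == "critical", ]
    expect_equal(crit$tpRate, 40 / 50)
    expect_equal(crit$fpRate, 20 / 150)
    expect_equal(crit$precision, 40 / 60)
})

test_that("MCC handles degenerate confusion matrices by convention", {
    expect_equal(mccScore(0, 0, 10, 0), 0)
    expect_equal(mccScore(5, 0, 0, 0), 0)
    expect_equal(mccScore(10, 0, 10, 0), 1)
    expect_equal(mccScore(0, 10, 0, 10), -1)
})

test_that("weighted recall equals overall accuracy", {
    set.seed(31)
    for (rep in 1:10) {
        truth <- factor(sample(c("critical", "non-critical"), 60, TRUE,
                               prob = c(0.3, 0.7)))
        pred <- factor(sample(c("critical", "non-critical"), 60, TRUE),
                       levels = levels(truth))
        r <- confusionMetrics(truth, pred)
        expect_equal(unname(r$weighted["recall"]), mean(truth == pred))
    }
})

test_that("ROC area matches the independent oracle and is monotone-invariant", {
    skip_if_not_installed("pROC")
    set.seed(32)
    for (rep in 1:10) {
        y <- factor(sample(c("critical", "non-critical"), 80, TRUE),
                    levels = c("critical", "non-critical"))
        s <- rnorm(80) + (y == "critical")
        got <- rocAreaScore(s, y, positive = "critical")
        oracle <- as.numeric(pROC::auc(pROC::roc(
            response = y, predictor = s, levels = c("non-critical", "critical"),
            direction = "<", quiet = TRUE)))
        expect_equal(got, oracle, tolerance = 1e-12)
        expect_equal(rocAreaScore(exp(3 * s), y, positive = "critical"), got)
    }
})

test_that("leave-one-out pools held-out predictions into one confusion", {
    ft <- makeFeatureTable(nInstances = 60, nInformative = 2, nNoise = 2,
                           classBalance = 0.3, effectSize = 3, seed = 33)
    spec <- classifierSpec(classWeights = c(critical = 9, "non-critical" = 3))
    rep <- leaveOneOut(ft, spec)
    expect_gte(unname(rep$weighted["mcc"]), 0.9)
    expect_equal(nrow(rep$predictions), 60L)
    ## label permutation kills the signal
    set.seed(34)
    ftPerm <- FeatureTable(featureValues(ft), sample(classLabels(ft)))
    repPerm <- leaveOneOut(ftPerm, spec)
    expect_lt(abs(unname(repPerm$weighted["mcc"])), 0.3)
})

test_that("the swapped test equals resubstitution when train = test and intersects descriptors", {
    ft <- makeFeatureTable(nInstances = 80, nInformative = 2, nNoise = 3,
                           classBalance = 0.3, seed = 35)
    spec <- classifierSpec(classWeights = c(critical = 9, "non-critical" = 3))
    swp <- swappedTest(ft, ft, spec)
    fit <- trainClassifier(spec, featureValues(ft), classLabels(ft))
    pr <- predictClassifier(fit, featureValues(ft))
    resub <- confusionMetrics(classLabels(ft), pr$labels, pr$scores)
    expect_equal(swp$weighted, resub$weighted)
    ## descriptor mismatch intersects with a warning
    ft2 <- FeatureTable(featureValues(ft)[, 1:3], classLabels(ft))
    expect_warning(swp2 <- swappedTest(ft, ft2, spec), "shared")
    expect_equal(nrow(swp2$predictions), 80L)
    ## transfer to label-independent data is a coin flip
    set.seed(36)
    ftNull <- FeatureTable(featureValues(ft),
                           sample(classLabels(ft)))
    null <- swappedTest(ft, ftNull, spec)
    expect_lt(abs(unname(null$weighted["rocArea"]) - 0.5), 0.17)
})

test_that("model overlap is row-normalized and asymmetric", {
    a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
    b <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
    ov <- modelOverlap(a, b)
    expect_equal(unname(ov), c(100, 75))
    expect_equal(unname(modelOverlap(a, a)), c(100, 100))
    expect_equal(unname(modelOverlap(a, !a)), c(0, 0))
    expect_true(is.na(modelOverlap(rep(FALSE, 6), b)[["aToB"]]))
    M <- modelOverlapMatrix(list(small = a, large = b))
    expect_equal(M["small", "large"], 100)
    expect_equal(M["large", "small"], 75)
    ## containment always gives 100 in the contained direction
    set.seed(37)
    for (rep in 1:10) {
        big <- runif(20) < 0.5
        sub <- big & (runif(20) < 0.7)
        if (!any(sub)) next
        expect_equal(modelOverlap(sub, big)[["aToB"]], 100)
    }
})

test_that("regression metrics give correlation and relative absolute error", {
    truth <- c(0.1, 0.4, 0.6, 0.9)
    m <- regressionMetrics(truth, truth)
    expect_equal(unname(m["correlation"]), 1)
    expect_equal(unname(m["relativeAbsoluteError"]), 0)
    mMean <- regressionMetrics(truth, rep(mean(truth), 4))
    expect_equal(unname(mMean["relativeAbsoluteError"]), 100)
})
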