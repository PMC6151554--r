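## Classifier contract, classification metrics and the evaluation harnesses
## (leave-one-out, swapped-set, model overlap).

#' Declare a classifier
#'
#' The evaluation harnesses and the genetic-algorithm wrapper are
#' classifier-agnostic: they consume a declared contract (name,
#' hyperparameters, class weights).  The packaged classifier is a
#' class-weighted linear-margin support vector machine; the per-class
#' weights rescale the penalty cost C to counter class imbalance.
#'
#' @param classWeights named numeric vector of per-class penalty weights
#'   (names must match the class levels), e.g. `c(critical = 9,
#'   "non-critical" = 3)`.
#' @param cost base penalty cost C (default 1).
#' @param positiveClass class whose decision scores are reported (default:
#'   first level of the training labels).
#' @return list of class `classifierSpec`.
#' @export
classifierSpec <- function(classWeights = NULL, cost = 1, positiveClass = NULL) {
    structure(list(name = "weightedLinearSVM", classWeights = classWeights,
                   cost = cost, positiveClass = positiveClass),
              class = "classifierSpec")
}

#' @rdname classifierSpec
#' @param spec a `classifierSpec`.
#' @param x numeric matrix of descriptors.
#' @param y binary factor of labels.
#' @return `trainClassifier`: a fitted classifier object.
#' @export
trainClassifier <- function(spec, x, y) {
    y <- droplevels(factor(y))
    if (nlevels(y) < 2L) stop("training labels contain a single class")
    w <- spec$classWeights
    if (!is.null(w)) {
        if (!all(levels(y) %in% names(w)))
            stop("classWeights must name every class level")
        w <- w[levels(y)]
    }
    model <- e1071::svm(x = x, y = y, kernel = "linear", cost = spec$cost,
                        class.weights = w, scale = FALSE)
    pos <- if (is.null(spec$positiveClass)) levels(y)[1L] else spec$positiveClass
    structure(list(spec = spec, model = model, positiveClass = pos),
              class = "trainedClassifier")
}

#' @rdname classifierSpec
#' @param fit a fitted classifier from `trainClassifier`.
#' @param newx numeric matrix of descriptors to predict.
#' @return `predictClassifier`: list with `labels` (factor) and `scores`
#'   (signed distance to the separating boundary, positive toward the
#'   positive class).
#' @export
predictClassifier <- function(fit, newx) {
    pr <- stats::predict(fit$model, newx, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    score <- dv[, 1L]
    ## libsvm labels the decision column "<levA>/<levB>": positive scores
    ## point toward levA
    levA <- strsplit(colnames(dv)[1L], "/")[[1L]][1L]
    if (levA != fit$positiveClass) score <- -score
    list(labels = pr, scores = unname(score))
}

#' Matthews correlation coefficient from confusion counts
#'
#' Defined as 0 when any marginal is empty (zero denominator), the standard
#' convention that keeps fold averages defined.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return numeric(1) in `[-1, 1]`.
#' @export
mccScore <- function(tp, fp, tn, fn) {
    denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (denom == 0) return(0)
    (tp * tn - fp * fn) / denom
}

#' ROC area by the rank statistic
#'
#' The probability that a random positive scores above a random negative
#' (ties counted half), computed from average ranks; invariant under
#' strictly monotone transforms of the scores.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary factor or logical (TRUE / first level = positive).
#' @param positive the positive class label.
#' @return numeric(1) in `[0, 1]`.
#' @export
rocAreaScore <- function(scores, labels, positive = NULL) {
    if (is.logical(labels)) pos <- labels
    else {
        labels <- factor(labels)
        if (is.null(positive)) positive <- levels(labels)[1L]
        pos <- labels == positive
    }
    nPos <- sum(pos); nNeg <- sum(!pos)
    if (nPos == 0L || nNeg == 0L) return(NA_real_)
    r <- rank(scores)
    (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Classification metrics from predictions
#'
#' Per-class one-vs-rest TP rate, FP rate, precision, recall, plus the
#' binary MCC and (when scores are supplied) the ROC area; the summary row
#' weights the per-class values by class support, the convention used for
#' reporting weighted averages.  For single-label binary classification the
#' weighted recall equals overall accuracy.
#'
#' @param truth factor of true labels.
#' @param pred factor of predicted labels (same levels).
#' @param scores optional numeric scores toward `positive` (ROC area is
#'   omitted without them).
#' @param positive the class scores point toward (default: first level).
#' @return list of class `metricReport`: `perClass` data.frame (one row per
#'   class), `weighted` named numeric vector, `counts` per-class confusion
#'   counts.
#' @examples
#' truth <- factor(rep(c("critical", "non-critical"), c(50, 150)))
#' pred <- truth
#' confusionMetrics(truth, pred)$weighted
#' @export
confusionMetrics <- function(truth, pred, scores = NULL, positive = NULL) {
    truth <- factor(truth)
    pred <- factor(pred, levels = levels(truth))
    stopifnot(length(truth) == length(pred))
    if (is.null(positive)) positive <- levels(truth)[1L]
    lev <- levels(truth)
    if (nlevels(truth) < 2L || length(unique(truth)) < 2L)
        warning("single-class truth: MCC set to 0")
    rows <- lapply(lev, function(cl) {
        tp <- sum(truth == cl & pred == cl)
        fp <- sum(truth != cl & pred == cl)
        fn <- sum(truth == cl & pred != cl)
        tn <- sum(truth != cl & pred != cl)
        roc <- if (is.null(scores)) NA_real_ else
            rocAreaScore(if (cl == positive) scores else -scores,
                         truth == cl, positive = TRUE)
        data.frame(class = cl, support = tp + fn,
                   tpRate = if (tp + fn > 0) tp / (tp + fn) else 0,
                   fpRate = if (fp + tn > 0) fp / (fp + tn) else 0,
                   precision = if (tp + fp > 0) tp / (tp + fp) else 0,
                   recall = if (tp + fn > 0) tp / (tp + fn) else 0,
                   mcc = mccScore(tp, fp, tn, fn),
                   rocArea = roc,
                   tp = tp, fp = fp, tn = tn, fn = fn,
                   stringsAsFactors = FALSE)
    })
    perClass <- do.call(rbind, rows)
    w <- perClass$support / sum(perClass$support)
    weighted <- c(tpRate = sum(w * perClass$tpRate),
                  fpRate = sum(w * perClass$fpRate),
                  precision = sum(w * perClass$precision),
                  recall = sum(w * perClass$recall),
                  mcc = sum(w * perClass$mcc),
                  rocArea = if (is.null(scores)) NA_real_ else
                      sum(w * perClass$rocArea))
    structure(list(perClass = perClass[, 1:8],
                   weighted = weighted,
                   counts = perClass[, c("class", "tp", "fp", "tn", "fn")]),
              class = "metricReport")
}

#' @export
print.metricReport <- function(x, ...) {
    cat("Per-class metrics:\n")
    print(x$perClass, row.names = FALSE, digits = 3)
    cat("Weighted averages:\n")
    print(round(x$weighted, 3))
    invisible(x)
}

#' Regression metrics (numeric targets)
#'
#' Pearson correlation and relative absolute error (percent) between
#' predicted and true numeric targets, the metric pair reported for
#' criticality-score regression.
#'
#' @param truth,pred numeric vectors.
#' @return named numeric vector `correlation`, `relativeAbsoluteError`.
#' @export
regressionMetrics <- function(truth, pred) {
    rae <- 100 * sum(abs(pred - truth)) / sum(abs(truth - mean(truth)))
    c(correlation = stats::cor(truth, pred), relativeAbsoluteError = rae)
}

#' Leave-one-out evaluation
#'
#' Fits the classifier n times, each time holding out one instance, and
#' pools all n held-out predictions into a single confusion matrix (fold
#' size 1 makes per-fold metrics degenerate).
#'
#' @param ft a [FeatureTable-class] with a binary factor class.
#' @param spec a [classifierSpec()].
#' @return `metricReport`, with the per-instance predictions in
#'   `$predictions`.
#' @export
leaveOneOut <- function(ft, spec = classifierSpec()) {
    x <- ft@values
    y <- ft@classLabel
    stopifnot(is.factor(y), nrow(x) >= 2L)
    n <- nrow(x)
    predLab <- character(n)
    score <- numeric(n)
    for (i in seq_len(n)) {
        fit <- trainClassifier(spec, x[-i, , drop = FALSE], y[-i])
        pr <- predictClassifier(fit, x[i, , drop = FALSE])
        predLab[i] <- as.character(pr$labels)
        score[i] <- pr$scores
    }
    pred <- factor(predLab, levels = levels(y))
    rep <- confusionMetrics(y, pred, score,
                            positive = if (is.null(spec$positiveClass))
                                levels(y)[1L] else spec$positiveClass)
    rep$predictions <- data.frame(ft@ids, true = y, predicted = pred,
                                  score = score)
    rep
}

#' Swapped-set evaluation
#'
#' Trains on one feature table and evaluates on another (e.g. datasets with
#' labels derived under different criticality definitions).  Descriptor
#' columns are intersected (with a warning when the sets differ), mirroring
#' cross-dataset transfer where the descriptor panels need not coincide.
#'
#' @param trainFt,testFt [FeatureTable-class] objects with binary classes
#'   on the same level set.
#' @param spec a [classifierSpec()].
#' @return `metricReport` on the test table, predictions attached.
#' @export
swappedTest <- function(trainFt, testFt, spec = classifierSpec()) {
    shared <- intersect(descriptorNames(trainFt), descriptorNames(testFt))
    if (!length(shared)) stop("no shared descriptors between the tables")
    if (length(shared) < length(descriptorNames(trainFt)) ||
        length(shared) < length(descriptorNames(testFt)))
        warning("descriptor sets differ; using the ", length(shared),
                " shared descriptors")
    fit <- trainClassifier(spec, trainFt@values[, shared, drop = FALSE],
                           trainFt@classLabel)
    pr <- predictClassifier(fit, testFt@values[, shared, drop = FALSE])
    truth <- factor(testFt@classLabel, levels = levels(factor(trainFt@classLabel)))
    rep <- confusionMetrics(truth, factor(pr$labels, levels = levels(truth)),
                            pr$scores, positive = fit$positiveClass)
    rep$predictions <- data.frame(testFt@ids, true = truth,
                                  predicted = pr$labels, score = pr$scores)
    rep
}

#' Overlap of critical-residue classifications between two models
#'
#' The number of residues both models call critical, normalized by the
#' number each model itself calls critical — hence asymmetric: if model a's
#' critical set is contained in model b's larger set, a-to-b is 100 percent
#' while b-to-a is smaller.  A model with no critical calls has undefined
#' overlap (`NA`).
#'
#' @param predA,predB per-instance classifications (factors with a
#'   `critical` level, or logicals meaning "called critical"), aligned on
#'   the same instances.
#' @return named numeric vector, percentages `aToB` and `bToA`.
#' @examples
#' a <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
#' b <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
#' modelOverlap(a, b)   # 100 vs 75
#' @export
modelOverlap <- function(predA, predB) {
    asCrit <- function(p) if (is.logical(p)) p else
        factor(p) == "critical"
    a <- asCrit(predA); b <- asCrit(predB)
    stopifnot(length(a) == length(b))
    both <- sum(a & b)
    c(aToB = if (sum(a) == 0L) NA_real_ else 100 * both / sum(a),
      bToA = if (sum(b) == 0L) NA_real_ else 100 * both / sum(b))
}

#' Pairwise overlap matrix for several models
#'
#' @param preds named list of per-instance classifications (see
#'   [modelOverlap()]).
#' @return square matrix; entry (r, c) is the percentage of model r's
#'   critical calls shared with model c (rows normalize).
#' @export
modelOverlapMatrix <- function(preds) {
    k <- length(preds)
    out <- matrix(NA_real_, k, k, dimnames = list(names(preds), names(preds)))
    for (r in seq_len(k)) for (cc in seq_len(k))
        out[r, cc] <- modelOverlap(preds[[r]], preds[[cc]])[["aToB"]]
    out
}
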