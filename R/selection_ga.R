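## Genetic-algorithm wrapper for descriptor-subset selection.
##
## Chromosomes are non-empty index subsets of the descriptor columns.  The
## fitness of a chromosome is the mean Matthews correlation coefficient of a
## class-weighted linear SVM over stratified 10-fold cross-validation on the
## selected columns.  Search uses binary tournament selection with
## replacement, subset-size-oriented common-feature (SSOCF) crossover,
## index-toggle mutation and elitism.

#' Class-weight presets for the weighted SVM
#'
#' Named penalty-weight pairs for the critical / non-critical classes used
#' with strongly imbalanced residue datasets: `"set1"` is (9, 3) and
#' `"set3"` is (5, 1.22).  Any named numeric vector may be used instead.
#'
#' @param name `"set1"` or `"set3"`.
#' @return named numeric vector of class weights.
#' @export
classWeightPreset <- function(name = c("set1", "set3")) {
    name <- match.arg(name)
    switch(name,
           set1 = c(critical = 9, "non-critical" = 3),
           set3 = c(critical = 5, "non-critical" = 1.22))
}

#' Genetic-algorithm configuration
#'
#' @param populationSize chromosomes per generation (default 50).
#' @param crossoverProb SSOCF crossover probability (default 0.7).
#' @param mutationProb per-offspring toggle-mutation probability (default
#'   0.1).
#' @param elitism number of best chromosomes copied unchanged into the next
#'   generation (default 1).
#' @param maxGenerations generation cap (default 100).
#' @param stagnation stop after this many generations without improvement of
#'   the best-ever fitness (default 20).
#' @param cvFolds cross-validation folds for the fitness (default 10).
#' @param classWeights per-class SVM penalty weights (default
#'   `classWeightPreset("set1")`).
#' @param cost base SVM penalty cost C (default 1).
#' @return list of class `gaControl`.
#' @export
gaControl <- function(populationSize = 50L, crossoverProb = 0.7,
                      mutationProb = 0.1, elitism = 1L,
                      maxGenerations = 100L, stagnation = 20L,
                      cvFolds = 10L, classWeights = classWeightPreset("set1"),
                      cost = 1) {
    stopifnot(populationSize >= 2L, crossoverProb >= 0, crossoverProb <= 1,
              mutationProb >= 0, mutationProb <= 1, elitism >= 0L,
              maxGenerations >= 1L, cvFolds >= 2L)
    structure(list(populationSize = as.integer(populationSize),
                   crossoverProb = crossoverProb, mutationProb = mutationProb,
                   elitism = as.integer(elitism),
                   maxGenerations = as.integer(maxGenerations),
                   stagnation = as.integer(stagnation),
                   cvFolds = as.integer(cvFolds),
                   classWeights = classWeights, cost = cost),
              class = "gaControl")
}

#' Initial random population
#'
#' Draws `populationSize` chromosomes with sizes uniform on
#' `[1, floor(m/10)]` and indices sampled without replacement; with fewer
#' than 10 descriptors the size range clamps to `[1, 1]` with a warning.
#'
#' @param m number of descriptors.
#' @param control a [gaControl()].
#' @return list of integer vectors (sorted, no duplicates).
#' @export
initPopulation <- function(m, control = gaControl()) {
    maxSize <- floor(m / 10)
    if (maxSize < 1L) {
        warning("fewer than 10 descriptors: initial sizes clamp to 1")
        maxSize <- 1L
    }
    lapply(seq_len(control$populationSize), function(k) {
        size <- sample.int(maxSize, 1L)
        sort(sample.int(m, size))
    })
}

#' Binary tournament selection with replacement
#'
#' Draws two chromosomes with replacement and returns the fitter one; ties
#' go to the smaller subset, then to the first drawn.
#'
#' @param population list of chromosomes.
#' @param fitness numeric vector of their fitness values.
#' @return the winning chromosome (integer vector).
#' @export
tournamentSelect <- function(population, fitness) {
    idx <- sample.int(length(population), 2L, replace = TRUE)
    f <- fitness[idx]
    len <- lengths(population[idx])
    win <- if (f[1L] > f[2L]) 1L
           else if (f[2L] > f[1L]) 2L
           else if (len[1L] <= len[2L]) 1L else 2L
    population[[idx[win]]]
}

#' Subset-size-oriented common-feature crossover
#'
#' Both children inherit all features common to the parents; the
#' non-shared features are partitioned at random so that each child has
#' exactly its corresponding parent's size.  Identical parents yield
#' copies.
#'
#' @param p1,p2 parent chromosomes (non-empty integer vectors).
#' @return list of two children.
#' @export
ssocfCrossover <- function(p1, p2) {
    stopifnot(length(p1) > 0L, length(p2) > 0L)
    common <- intersect(p1, p2)
    pool <- setdiff(union(p1, p2), common)
    if (!length(pool)) return(list(sort(p1), sort(p2)))
    n1 <- length(p1) - length(common)
    take <- pool[sample.int(length(pool), n1)]
    list(sort(c(common, take)), sort(c(common, setdiff(pool, take))))
}

#' Index-toggle mutation
#'
#' With probability `prob`, draws one descriptor index uniformly and
#' toggles its membership; a removal that would empty the chromosome
#' re-draws instead, so chromosomes stay non-empty.
#'
#' @param chrom chromosome (integer vector).
#' @param m number of descriptors.
#' @param prob mutation probability (default 0.1).
#' @return possibly mutated chromosome.
#' @export
mutateChromosome <- function(chrom, m, prob = 0.1) {
    if (stats::runif(1L) >= prob) return(chrom)
    repeat {
        idx <- sample.int(m, 1L)
        if (!(idx %in% chrom && length(chrom) == 1L)) break
    }
    if (idx %in% chrom) sort(setdiff(chrom, idx)) else sort(c(chrom, idx))
}

## Stratified fold assignment: within each class, shuffled indices are dealt
## round-robin, so every training fold keeps both classes.
makeStratifiedFolds <- function(y, k) {
    folds <- integer(length(y))
    for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
}

#' Cross-validated fitness of a chromosome
#'
#' Trains the class-weighted linear SVM on the selected descriptor columns
#' and returns the mean Matthews correlation coefficient over stratified
#' cross-validation folds (a fold with a degenerate confusion matrix scores
#' 0).
#'
#' @param chrom chromosome (descriptor column indices).
#' @param ft a [FeatureTable-class] with a binary factor class.
#' @param control a [gaControl()].
#' @param folds optional fixed fold assignment (integer vector); drawn from
#'   the current RNG state when missing.
#' @return list with `chromosome`, `mcc` (mean), `foldMccs`, `size`.
#' @export
chromosomeFitness <- function(chrom, ft, control = gaControl(), folds = NULL) {
    x <- ft@values
    y <- ft@classLabel
    if (!is.factor(y) || nlevels(droplevels(y)) < 2L)
        stop("fitness needs a two-class factor label")
    stopifnot(all(chrom >= 1L), all(chrom <= ncol(x)))
    if (is.null(folds)) folds <- makeStratifiedFolds(y, control$cvFolds)
    spec <- classifierSpec(classWeights = control$classWeights,
                           cost = control$cost,
                           positiveClass = levels(y)[1L])
    xs <- x[, chrom, drop = FALSE]
    foldMccs <- vapply(seq_len(control$cvFolds), function(f) {
        test <- folds == f
        if (!any(test)) return(NA_real_)
        fit <- trainClassifier(spec, xs[!test, , drop = FALSE], y[!test])
        pred <- predictClassifier(fit, xs[test, , drop = FALSE])$labels
        tp <- sum(y[test] == levels(y)[1L] & pred == levels(y)[1L])
        fp <- sum(y[test] != levels(y)[1L] & pred == levels(y)[1L])
        fn <- sum(y[test] == levels(y)[1L] & pred != levels(y)[1L])
        tn <- sum(y[test] != levels(y)[1L] & pred != levels(y)[1L])
        mccScore(tp, fp, tn, fn)
    }, numeric(1))
    foldMccs <- foldMccs[!is.na(foldMccs)]
    list(chromosome = chrom, mcc = mean(foldMccs), foldMccs = foldMccs,
         size = length(chrom))
}

#' Evolve a descriptor subset
#'
#' Runs the generational genetic algorithm: elites are copied unchanged,
#' the remainder of each generation is produced by tournament selection,
#' SSOCF crossover and toggle mutation; fitness values are cached per
#' subset, and the fold assignment is drawn once per run so fitness is a
#' pure function of the subset.  Stops at the generation cap or after a
#' stagnation window without improvement.  Fully reproducible for a given
#' seed and table.
#'
#' @param ft a filtered [FeatureTable-class] with a binary factor class.
#' @param control a [gaControl()].
#' @param seed integer RNG seed.
#' @return list of class `gaSelection`: `best` (fitness record of the
#'   best-ever chromosome, with descriptor names), `history` (per-generation
#'   best / mean MCC), `generations`, `control`, `seed`.
#' @examples
#' \donttest{
#' ft <- makeFeatureTable(nInstances = 120, nInformative = 3, nNoise = 17,
#'                        seed = 7)
#' sel <- gaSelect(ft, gaControl(maxGenerations = 10), seed = 1)
#' sel$best$names
#' }
#' @export
gaSelect <- function(ft, control = gaControl(), seed = 1L) {
    set.seed(seed)
    m <- ncol(ft@values)
    if (m < 1L)
        stop("no descriptors to select from (did the filters remove ",
             "every column?)")
    folds <- makeStratifiedFolds(ft@classLabel, control$cvFolds)
    cache <- new.env(parent = emptyenv())
    evalChrom <- function(chrom) {
        key <- paste(chrom, collapse = ",")
        if (!is.null(cache[[key]])) return(cache[[key]])
        rec <- chromosomeFitness(chrom, ft, control, folds)
        cache[[key]] <- rec
        rec
    }
    population <- initPopulation(m, control)
    records <- lapply(population, evalChrom)
    fitness <- vapply(records, `[[`, numeric(1), "mcc")
    best <- records[[order(-fitness, lengths(population))[1L]]]
    history <- data.frame(generation = 0L, bestMCC = best$mcc,
                          meanMCC = mean(fitness))
    stagnant <- 0L
    gen <- 0L
    while (gen < control$maxGenerations && stagnant < control$stagnation) {
        gen <- gen + 1L
        ord <- order(-fitness, lengths(population))
        nextPop <- population[ord[seq_len(min(control$elitism,
                                              length(population)))]]
        while (length(nextPop) < control$populationSize) {
            p1 <- tournamentSelect(population, fitness)
            p2 <- tournamentSelect(population, fitness)
            children <- if (stats::runif(1L) < control$crossoverProb)
                ssocfCrossover(p1, p2) else list(p1, p2)
            children <- lapply(children, mutateChromosome, m = m,
                               prob = control$mutationProb)
            room <- control$populationSize - length(nextPop)
            nextPop <- c(nextPop, children[seq_len(min(2L, room))])
        }
        population <- nextPop
        records <- lapply(population, evalChrom)
        fitness <- vapply(records, `[[`, numeric(1), "mcc")
        genBest <- records[[order(-fitness, lengths(population))[1L]]]
        if (genBest$mcc > best$mcc) {
            best <- genBest
            stagnant <- 0L
        } else stagnant <- stagnant + 1L
        history <- rbind(history,
                         data.frame(generation = gen, bestMCC = best$mcc,
                                    meanMCC = mean(fitness)))
    }
    best$names <- colnames(ft@values)[best$chromosome]
    structure(list(best = best, history = history, generations = gen,
                   control = control, seed = seed),
              class = "gaSelection")
}

#' @export
print.gaSelection <- function(x, ...) {
    cat(sprintf("GA descriptor selection: %d generations, best CV MCC %.3f\n",
                x$generations, x$best$mcc))
    cat(" selected (", x$best$size, "): ",
        paste(x$best$names, collapse = ", "), "\n", sep = "")
    invisible(x)
}

#' Write a GA selection report as JSON
#'
#' Includes the per-generation best / mean fitness trajectory and the final
#' descriptor-name subset.
#'
#' @param sel a `gaSelection` result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGAReport <- function(sel, path) {
    jsonlite::write_json(
        list(seed = sel$seed, generations = sel$generations,
             bestMCC = sel$best$mcc, subsetSize = sel$best$size,
             selected = sel$best$names, history = sel$history),
        path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    invisible(path)
}
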