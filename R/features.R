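## Feature-table I/O and the three-stage descriptor filter:
## constant removal -> Spearman redundancy -> information-gain relevance.

#' Read / write a feature table (CSV or ARFF)
#'
#' CSV files need a header; ARFF is read and written through the `foreign`
#' package.  The class column (named `classColumn`, default `"class"`) may
#' be a two-level nominal / character column (coerced to factor) or numeric
#' (a regression target such as a criticality index).  All other columns
#' must be numeric descriptors.  Round-tripping through either format
#' preserves descriptor values.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"csv"` or `"arff"`.
#' @param classColumn name of the class column (default `"class"`).
#' @param idColumns optional character vector of identifier columns to carry
#'   as instance ids rather than descriptors.
#' @return A [FeatureTable-class].
#' @export
readFeatureTable <- function(path, format = c("auto", "csv", "arff"),
                             classColumn = "class", idColumns = NULL) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
    df <- if (format == "arff") foreign::read.arff(path) else
        utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!classColumn %in% names(df))
        stop("class column '", classColumn, "' not found in ", path)
    y <- df[[classColumn]]
    if (is.character(y)) y <- factor(y)
    ids <- if (is.null(idColumns)) data.frame(instance = seq_len(nrow(df)))
           else df[, idColumns, drop = FALSE]
    keep <- setdiff(names(df), c(classColumn, idColumns))
    xdf <- df[, keep, drop = FALSE]
    bad <- names(xdf)[!vapply(xdf, is.numeric, logical(1))]
    if (length(bad))
        stop("non-numeric descriptor column(s): ", paste(bad, collapse = ", "))
    x <- as.matrix(xdf)
    if (anyNA(x))
        stop("missing descriptor values in ", path,
             "; impute or drop rows before ingestion")
    FeatureTable(x, y, ids)
}

#' @rdname readFeatureTable
#' @param ft a [FeatureTable-class] to write.
#' @export
writeFeatureTable <- function(ft, path, format = c("auto", "csv", "arff"),
                              classColumn = "class") {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
    df <- as.data.frame(ft@values, check.names = FALSE)
    y <- ft@classLabel
    if (is.factor(y)) {
        ## ARFF nominal names cannot contain spaces/hyphens in some readers;
        ## keep levels as-is for CSV, sanitize only for ARFF.
        if (format == "arff")
            levels(y) <- gsub("[^A-Za-z0-9_]", "_", levels(y))
    }
    df[[classColumn]] <- y
    if (format == "arff") {
        names(df) <- gsub("[^A-Za-z0-9_.]", "_", names(df))
        foreign::write.arff(df, path)
    } else {
        utils::write.csv(df, path, row.names = FALSE)
    }
    invisible(path)
}

#' Remove constant (useless) descriptors
#'
#' Drops exactly the descriptors that do not vary across instances; they
#' carry no information about any class.  The removal report is appended to
#' the table's [filterLog()].
#'
#' @param ft a [FeatureTable-class].
#' @return filtered [FeatureTable-class].
#' @export
removeUseless <- function(ft) {
    x <- ft@values
    if (nrow(x) < 1L) stop("need at least one instance")
    constant <- apply(x, 2L, function(col) all(col == col[1L]))
    ftKeepColumns(ft, !constant,
                  list(filter = "remove_useless",
                       removed = colnames(x)[constant]))
}

#' Spearman redundancy filter
#'
#' Walks the descriptors in column order and drops any descriptor whose
#' absolute Spearman rank correlation with an already-retained descriptor
#' reaches the threshold; the first-seen member of a correlated group is
#' kept.  Rank correlation makes the filter invariant to strictly monotone
#' transforms, so a monotone copy of a kept column is always removed.
#' Constant columns (undefined rho) are treated as uncorrelated and
#' flagged — they should have been removed by [removeUseless()] first.
#'
#' @param ft a [FeatureTable-class].
#' @param threshold absolute rank-correlation threshold (default 0.95).
#' @return filtered [FeatureTable-class].
#' @export
spearmanRedundancyFilter <- function(ft, threshold = 0.95) {
    x <- ft@values
    if (nrow(x) < 3L) stop("need at least 3 instances for rank correlations")
    p <- ncol(x)
    constant <- apply(x, 2L, function(col) all(col == col[1L]))
    if (any(constant))
        warning("constant column(s) reached the Spearman filter: ",
                paste(colnames(x)[constant], collapse = ", "))
    rx <- apply(x, 2L, rank)
    keep <- logical(p)
    for (j in seq_len(p)) {
        if (constant[j]) { keep[j] <- TRUE; next }
        kept <- which(keep & !constant)
        if (length(kept)) {
            rho <- suppressWarnings(
                abs(stats::cor(rx[, j], rx[, kept, drop = FALSE])))
            rho[is.na(rho)] <- 0
            if (any(rho >= threshold)) next
        }
        keep[j] <- TRUE
    }
    ftKeepColumns(ft, keep,
                  list(filter = "spearman_redundancy", threshold = threshold,
                       removed = colnames(x)[!keep]))
}

## Shannon entropy (bits) of a discrete vector.
shannonEntropy <- function(y) {
    p <- table(y)
    p <- p[p > 0] / length(y)
    -sum(p * log2(p))
}

#' Supervised MDL discretization (Fayyad-Irani)
#'
#' Recursively splits a numeric descriptor at the boundary maximizing
#' information gain about the class, stopping when the gain fails the
#' minimum-description-length criterion.  Returns the accepted cut points
#' (possibly none).
#'
#' @param x numeric vector.
#' @param y class factor.
#' @return numeric vector of cut points, sorted (length 0 if no cut is
#'   justified).
#' @export
mdlDiscretize <- function(x, y) {
    y <- factor(y)
    rec <- function(idx) {
        xi <- x[idx]; yi <- y[idx]
        n <- length(idx)
        if (n < 4L) return(numeric())
        ord <- order(xi)
        xs <- xi[ord]; ys <- yi[ord]
        ## candidate cuts: midpoints between distinct consecutive values
        distinct <- which(diff(xs) > 0)
        if (!length(distinct)) return(numeric())
        ent <- shannonEntropy(ys)
        k <- nlevels(droplevels(ys))
        ## cumulative class counts left of each cut
        Yc <- stats::model.matrix(~ ys - 1)
        cum <- apply(Yc, 2L, cumsum)
        bestGain <- -Inf; best <- NULL
        for (cpos in distinct) {
            n1 <- cpos; n2 <- n - cpos
            p1 <- cum[cpos, ]; p2 <- cum[n, ] - p1
            e1 <- { q <- p1[p1 > 0] / n1; -sum(q * log2(q)) }
            e2 <- { q <- p2[p2 > 0] / n2; -sum(q * log2(q)) }
            gain <- ent - (n1 * e1 + n2 * e2) / n
            if (gain > bestGain) {
                bestGain <- gain
                best <- list(cut = (xs[cpos] + xs[cpos + 1L]) / 2,
                             e1 = e1, e2 = e2,
                             k1 = sum(p1 > 0), k2 = sum(p2 > 0),
                             cpos = cpos)
            }
        }
        ## MDL acceptance test
        delta <- log2(3^k - 2) - (k * ent - best$k1 * best$e1 - best$k2 * best$e2)
        if (bestGain <= (log2(n - 1) + delta) / n) return(numeric())
        left <- idx[xi <= best$cut]
        right <- idx[xi > best$cut]
        sort(c(rec(left), best$cut, rec(right)))
    }
    rec(seq_along(x))
}

#' Information gain of a descriptor about a binary class
#'
#' The descriptor is discretized by [mdlDiscretize()]; when no cut is
#' accepted the gain is 0 by construction.
#'
#' @param x numeric descriptor.
#' @param y binary class factor.
#' @return numeric(1), information gain in bits.
#' @export
informationGain <- function(x, y) {
    cuts <- mdlDiscretize(x, y)
    if (!length(cuts)) return(0)
    bins <- cut(x, c(-Inf, cuts, Inf))
    shannonEntropy(y) -
        sum(vapply(split(y, bins), function(ys)
            length(ys) / length(y) * shannonEntropy(ys), numeric(1)))
}

#' Information-gain relevance filter
#'
#' Drops every descriptor whose information gain about the binary class is
#' zero after MDL discretization; pure-noise descriptors yield no accepted
#' cut and are removed, descriptors that separate the classes are kept.
#' Only defined for binary class columns; for numeric (regression) targets
#' use the binary datasets instead.
#'
#' @param ft a [FeatureTable-class] with a factor class column.
#' @return filtered [FeatureTable-class]; the report records each kept
#'   descriptor's gain.
#' @export
informationGainFilter <- function(ft) {
    y <- ft@classLabel
    if (!is.factor(y))
        stop("information-gain filter needs a binary class column; ",
             "numeric targets are not supported")
    x <- ft@values
    ig <- apply(x, 2L, informationGain, y = y)
    keep <- ig > 0
    ftKeepColumns(ft, keep,
                  list(filter = "information_gain",
                       removed = colnames(x)[!keep],
                       gain = ig[keep]))
}

#' The fixed descriptor-filter pipeline
#'
#' Applies the three filters in their fixed order — constant removal,
#' Spearman redundancy, information gain (the last only for binary class
#' columns) — and returns the filtered table with the full removal
#' provenance in [filterLog()].
#'
#' @param ft a [FeatureTable-class].
#' @param spearmanThreshold passed to [spearmanRedundancyFilter()].
#' @return filtered [FeatureTable-class].
#' @export
filterFeatures <- function(ft, spearmanThreshold = 0.95) {
    ft <- removeUseless(ft)
    ft <- spearmanRedundancyFilter(ft, spearmanThreshold)
    if (is.factor(ft@classLabel))
        ft <- informationGainFilter(ft)
    ft
}

#' Write filter reports as JSON
#'
#' @param ft a filtered [FeatureTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFilterReport <- function(ft, path) {
    jsonlite::write_json(ft@log, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
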