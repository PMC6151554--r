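#' @import methods
NULL

## One-letter codes of the 20 standard amino acids, alphabetical.
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' ChainStructure: one protein chain with heavy-atom coordinates
#'
#' Holds the ordered standard-amino-acid residues of a single chain of a PDB
#' entry, together with their heavy-atom coordinates.  Residues are indexed
#' 1..N in chain order (`seqIndex`); the original PDB numbering (`resno` plus
#' insertion code) is preserved for reporting.
#'
#' @slot pdbID character(1), identifier of the source entry (may be `""`).
#' @slot chainID character(1), the chain selected.
#' @slot residues data.frame with columns `seqIndex` (integer, contiguous
#'   1..N), `resno` (integer PDB residue number), `insert` (character
#'   insertion code, `""` if none) and `aa` (one-letter code, `X` for
#'   unmapped).
#' @slot atoms data.frame with columns `resIndex` (integer, pointing into
#'   `residues$seqIndex`), `name` (atom name, e.g. `"CA"`), `elem` (element
#'   symbol) and `x`, `y`, `z` (coordinates in Angstrom).
#'
#' @seealso [readChain()], [makeStructure()]
#' @exportClass ChainStructure
setClass("ChainStructure",
         representation(pdbID = "character", chainID = "character",
                        residues = "data.frame", atoms = "data.frame"))

setValidity("ChainStructure", function(object) {
    msg <- character()
    res <- object@residues
    atm <- object@atoms
    need <- c("seqIndex", "resno", "insert", "aa")
    if (!all(need %in% names(res)))
        return(paste("residues must have columns", paste(need, collapse = ", ")))
    if (!all(c("resIndex", "name", "elem", "x", "y", "z") %in% names(atm)))
        return("atoms must have columns resIndex, name, elem, x, y, z")
    n <- nrow(res)
    if (n < 1L) msg <- c(msg, "chain has no residues")
    if (n >= 1L && !identical(as.integer(res$seqIndex), seq_len(n)))
        msg <- c(msg, "seqIndex must be contiguous 1..N")
    if (!all(res$aa %in% c(AA_CODES, "X")))
        msg <- c(msg, "aa must be a standard one-letter code or 'X'")
    if (nrow(atm) > 0L) {
        if (!all(atm$resIndex %in% res$seqIndex))
            msg <- c(msg, "atom resIndex outside residue range")
        if (!all(is.finite(atm$x) & is.finite(atm$y) & is.finite(atm$z)))
            msg <- c(msg, "non-finite atom coordinates")
    }
    if (n >= 1L && !all(res$seqIndex %in% atm$resIndex))
        msg <- c(msg, "every residue needs at least one atom")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ResidueContactGraph: undirected residue contact graph
#'
#' Undirected, unweighted graph over the residues of one chain; an edge joins
#' two residues whose atoms (under the chosen atom mode) lie within the
#' distance cutoff.  Edges are stored once as pairs `i < j` of 1-based
#' residue indices.
#'
#' @slot nNodes integer(1), number of residues.
#' @slot edges two-column integer matrix, each row an edge with `i < j`.
#' @slot cutoff numeric(1), contact distance cutoff in Angstrom.
#' @slot atomMode character(1), one of `"heavy"`, `"CA"`, `"CB"`.
#' @slot minSeqSep integer(1), minimal sequence separation of contacts.
#'
#' @seealso [buildContactGraph()], [centralityProfile()]
#' @exportClass ResidueContactGraph
setClass("ResidueContactGraph",
         representation(nNodes = "integer", edges = "matrix",
                        cutoff = "numeric", atomMode = "character",
                        minSeqSep = "integer"))

setValidity("ResidueContactGraph", function(object) {
    e <- object@edges
    n <- object@nNodes
    if (length(n) != 1L || n < 1L) return("nNodes must be a positive integer")
    if (ncol(e) != 2L) return("edges must have two columns")
    if (nrow(e) > 0L) {
        if (!is.numeric(e)) return("edges must be numeric")
        if (any(e < 1L | e > n)) return("edge index out of range")
        if (any(e[, 1L] >= e[, 2L])) return("edges must satisfy i < j (no self-edges)")
        if (anyDuplicated(paste(e[, 1L], e[, 2L])))
            return("duplicate edges")
    }
    if (object@cutoff <= 0) return("cutoff must be positive")
    TRUE
})

#' SubstitutionRanking: the 380 ordered substitutions ranked by dissimilarity
#'
#' All 380 ordered pairs of distinct standard amino acids, scored by the
#' Euclidean distance between their five physicochemical factor vectors and
#' ranked ascending by distance, so rank 380 is the most dissimilar
#' substitution.
#'
#' @slot table data.frame with columns `from`, `to` (one-letter codes),
#'   `distance` (numeric) and `rank` (integer, permutation of 1..380).
#'
#' @seealso [buildSubstitutionRanking()], [annotateCriticality()]
#' @exportClass SubstitutionRanking
setClass("SubstitutionRanking", representation(table = "data.frame"))

setValidity("SubstitutionRanking", function(object) {
    tab <- object@table
    if (!all(c("from", "to", "distance", "rank") %in% names(tab)))
        return("table must have columns from, to, distance, rank")
    if (nrow(tab) != 380L) return("table must have exactly 380 rows")
    if (any(tab$from == tab$to)) return("identity pairs are not substitutions")
    if (!identical(sort(as.integer(tab$rank)), 1:380))
        return("ranks must be a permutation of 1..380")
    d <- tab$distance[order(tab$rank)]
    if (any(diff(d) < -1e-12)) return("distance must be non-decreasing in rank")
    TRUE
})

#' FeatureTable: residues-by-descriptors matrix with a class column
#'
#' The object the filters, the genetic-algorithm wrapper and the evaluation
#' harness operate on: one row per instance (residue), one column per
#' descriptor, plus a class column that is either a two-level factor
#' (critical / non-critical) or a numeric target (criticality index).
#'
#' @slot values numeric matrix, instances x descriptors, with unique column
#'   names.
#' @slot classLabel factor (binary) or numeric vector, one entry per row.
#' @slot ids data.frame of instance identifiers (one row per instance).
#' @slot log list of filter reports accumulated by the filter functions.
#'
#' @seealso [readFeatureTable()], [removeUseless()], [gaSelect()]
#' @exportClass FeatureTable
setClass("FeatureTable",
         representation(values = "matrix", classLabel = "ANY",
                        ids = "data.frame", log = "list"))

setValidity("FeatureTable", function(object) {
    x <- object@values
    y <- object@classLabel
    if (!is.numeric(x)) return("values must be a numeric matrix")
    if (ncol(x) > 0L && (is.null(colnames(x)) || anyDuplicated(colnames(x))))
        return("descriptor names must exist and be unique")
    if (length(y) != nrow(x)) return("class length must equal number of rows")
    if (anyNA(x)) return("missing descriptor values are not allowed")
    if (is.factor(y)) {
        if (nlevels(y) != 2L) return("factor class must have exactly 2 levels")
    } else if (!is.numeric(y)) {
        return("class must be a binary factor or numeric")
    }
    if (nrow(object@ids) != nrow(x)) return("ids must have one row per instance")
    TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix (instances x descriptors) with column names.
#' @param classLabel binary factor or numeric target, length `nrow(values)`.
#' @param ids optional data.frame of instance identifiers; defaults to row
#'   numbers.
#' @return A [FeatureTable-class] object.
#' @examples
#' x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("d1", "d2")))
#' ft <- FeatureTable(x, factor(rep(c("critical", "non-critical"), 5)))
#' dim(ft)
#' @export
FeatureTable <- function(values, classLabel, ids = NULL) {
    if (is.null(ids))
        ids <- data.frame(instance = seq_len(nrow(values)))
    if (is.character(classLabel)) classLabel <- factor(classLabel)
    new("FeatureTable", values = values, classLabel = classLabel,
        ids = ids, log = list())
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "ChainStructure", function(object) {
    cat(sprintf("ChainStructure %s chain %s: %d residues, %d atoms\n",
                ifelse(nzchar(object@pdbID), object@pdbID, "<unnamed>"),
                object@chainID, nrow(object@residues), nrow(object@atoms)))
    cat(" sequence:", substr(chainSequence(object), 1, 60),
        if (nrow(object@residues) > 60) "...\n" else "\n")
})

setMethod("show", "ResidueContactGraph", function(object) {
    cat(sprintf(paste0("ResidueContactGraph: %d residues, %d contacts ",
                       "(cutoff %.2f A, mode %s, min. separation %d)\n"),
                object@nNodes, nrow(object@edges), object@cutoff,
                object@atomMode, object@minSeqSep))
})

setMethod("show", "SubstitutionRanking", function(object) {
    tab <- object@table[order(object@table$rank), ]
    cat("SubstitutionRanking: 380 ordered substitutions\n")
    cat(sprintf(" least dissimilar: %s->%s (rank 1, d = %.3f)\n",
                tab$from[1], tab$to[1], tab$distance[1]))
    cat(sprintf(" most dissimilar:  %s->%s (rank 380, d = %.3f)\n",
                tab$from[380], tab$to[380], tab$distance[380]))
})

setMethod("show", "FeatureTable", function(object) {
    y <- object@classLabel
    cls <- if (is.factor(y)) {
        paste(sprintf("%s: %d", levels(y), tabulate(y, nlevels(y))),
              collapse = ", ")
    } else sprintf("numeric target in [%.3g, %.3g]", min(y), max(y))
    cat(sprintf("FeatureTable: %d instances x %d descriptors (%s)\n",
                nrow(object@values), ncol(object@values), cls))
    if (length(object@log))
        cat(" filters applied:", paste(vapply(object@log, `[[`, "", "filter"),
                                       collapse = " -> "), "\n")
})

## ---- generics and simple accessors ----------------------------------------

#' Number of residues in a chain
#' @param x a [ChainStructure-class].
#' @return integer(1).
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname nResidues
#' @export
setMethod("nResidues", "ChainStructure", function(x) nrow(x@residues))

#' One-letter amino-acid sequence of a chain
#' @param x a [ChainStructure-class].
#' @return character(1).
#' @export
setGeneric("chainSequence", function(x) standardGeneric("chainSequence"))

#' @rdname chainSequence
#' @export
setMethod("chainSequence", "ChainStructure",
          function(x) paste(x@residues$aa, collapse = ""))

#' Original PDB numbering of a chain's residues
#' @param x a [ChainStructure-class].
#' @return character vector, residue number pasted with insertion code.
#' @export
setGeneric("pdbNumbering", function(x) standardGeneric("pdbNumbering"))

#' @rdname pdbNumbering
#' @export
setMethod("pdbNumbering", "ChainStructure",
          function(x) paste0(x@residues$resno, x@residues$insert))

#' Residue table of a chain
#' @param x a [ChainStructure-class].
#' @return data.frame with columns seqIndex, resno, insert, aa.
#' @export
setGeneric("residueData", function(x) standardGeneric("residueData"))

#' @rdname residueData
#' @export
setMethod("residueData", "ChainStructure", function(x) x@residues)

#' @describeIn FeatureTable dimensions (instances, descriptors).
#' @param x a `FeatureTable`.
#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))

#' Descriptor matrix of a FeatureTable
#' @param x a [FeatureTable-class].
#' @return numeric matrix.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureTable", function(x) x@values)

#' Class column of a FeatureTable
#' @param x a [FeatureTable-class].
#' @return binary factor or numeric vector.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname classLabels
#' @export
setMethod("classLabels", "FeatureTable", function(x) x@classLabel)

#' Descriptor names of a FeatureTable
#' @param x a [FeatureTable-class].
#' @return character vector.
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' @rdname descriptorNames
#' @export
setMethod("descriptorNames", "FeatureTable", function(x) colnames(x@values))

#' Instance identifiers of a FeatureTable
#' @param x a [FeatureTable-class].
#' @return data.frame.
#' @export
setGeneric("instanceIds", function(x) standardGeneric("instanceIds"))

#' @rdname instanceIds
#' @export
setMethod("instanceIds", "FeatureTable", function(x) x@ids)

#' Filter provenance log of a FeatureTable
#'
#' Each filter ([removeUseless()], [spearmanRedundancyFilter()],
#' [informationGainFilter()]) appends a report listing the descriptors it
#' dropped.
#'
#' @param x a [FeatureTable-class].
#' @return list of reports (`filter`, `removed`, plus filter-specific fields).
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))

#' @rdname filterLog
#' @export
setMethod("filterLog", "FeatureTable", function(x) x@log)

#' Ranking table of a SubstitutionRanking
#' @param x a [SubstitutionRanking-class].
#' @return data.frame ordered by rank.
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname rankingTable
#' @export
setMethod("rankingTable", "SubstitutionRanking", function(x) {
    tab <- x@table[order(x@table$rank), ]
    rownames(tab) <- NULL
    tab
})

## Internal: subset a FeatureTable's descriptor columns, preserving log.
ftKeepColumns <- function(ft, keep, report) {
    x <- ft@values[, keep, drop = FALSE]
    new("FeatureTable", values = x, classLabel = ft@classLabel,
        ids = ft@ids, log = c(ft@log, list(report)))
}
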