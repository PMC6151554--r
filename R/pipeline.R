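## End-to-end pipeline: structure descriptors -> criticality labels ->
## dataset assembly -> filters -> GA selection -> evaluation.

#' Compute per-residue structure descriptors
#'
#' Builds the contact graph of a chain and computes the 11 centrality
#' descriptors, plus the correlated-mutation index when an alignment is
#' supplied (without one the CM column is omitted with a warning).
#'
#' @param chain a [ChainStructure-class] (or a PDB path, read with
#'   [readChain()]).
#' @param msa optional alignment matrix from [readMSA()] (or a FASTA path).
#' @param chainID chain to read when `chain` is a path.
#' @param cutoff,atomMode,minSeqSep contact definition, see
#'   [buildContactGraph()].
#' @param out optional CSV output path.
#' @return data.frame keyed by internal index and PDB numbering with the
#'   descriptor columns.
#' @export
runDescriptors <- function(chain, msa = NULL, chainID = "A", cutoff = 5,
                           atomMode = "heavy", minSeqSep = 1L, out = NULL) {
    if (is.character(chain)) chain <- readChain(chain, chainID)
    g <- buildContactGraph(chain, cutoff = cutoff, atomMode = atomMode,
                           minSeqSep = minSeqSep)
    prof <- centralityProfile(g)
    res <- cbind(data.frame(seqIndex = seq_len(nResidues(chain)),
                            pdbNumber = pdbNumbering(chain),
                            aa = chain@residues$aa,
                            stringsAsFactors = FALSE),
                 prof)
    if (is.null(msa)) {
        warning("no alignment supplied: correlated-mutation column omitted")
    } else {
        if (is.character(msa) && !is.matrix(msa)) msa <- readMSA(msa)
        sp <- substitutionProfile(chain, msa)
        res$CM <- correlatedMutationIndex(g, sp$S)
    }
    if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
    res
}

#' Score and label residues from a mutagenesis table
#'
#' @param muts mutagenesis data.frame or CSV/TSV path (see
#'   [readMutagenesis()]).
#' @param ranking a [SubstitutionRanking-class] (default: built from the
#'   packaged factor table).
#' @param strict use the literal denominator bounds (see [ciFromRanks()]).
#' @param out optional CSV output path.
#' @return data.frame `position`, `m`, `CI`, `label` for covered positions.
#' @export
runCriticalityLabels <- function(muts, ranking = buildSubstitutionRanking(),
                                 strict = FALSE, out = NULL) {
    if (is.character(muts)) muts <- readMutagenesis(muts)
    ann <- annotateCriticality(muts, ranking, strict = strict)
    if (!is.null(out)) utils::write.csv(ann, out, row.names = FALSE)
    ann
}

#' Assemble a feature table from descriptors and labels
#'
#' Joins per-residue descriptors with criticality labels on position
#' (internal index against label position) and optionally merges external
#' descriptor tables (e.g. physicochemical descriptor exports) by column
#' union on the shared positions.  Only labeled positions enter the table;
#' unlabeled residues are dropped, not fabricated.
#'
#' @param descriptors data.frame from [runDescriptors()].
#' @param labels data.frame from [runCriticalityLabels()].
#' @param external optional named list of data.frames with a `position`
#'   column plus numeric descriptor columns.
#' @param target `"binary"` uses the critical / non-critical label,
#'   `"numeric"` the CI value (regression target).
#' @return A [FeatureTable-class].
#' @export
assembleDataset <- function(descriptors, labels, external = list(),
                            target = c("binary", "numeric")) {
    target <- match.arg(target)
    idx <- match(labels$position, descriptors$seqIndex)
    if (anyNA(idx))
        stop("labelled position(s) missing from the descriptor table: ",
             paste(labels$position[is.na(idx)], collapse = ", "))
    numCols <- names(descriptors)[vapply(descriptors, is.numeric, logical(1))]
    numCols <- setdiff(numCols, "seqIndex")
    x <- as.matrix(descriptors[idx, numCols, drop = FALSE])
    for (nm in names(external)) {
        ext <- external[[nm]]
        eidx <- match(labels$position, ext$position)
        if (anyNA(eidx))
            stop("external table '", nm, "' misses labelled position(s)")
        ecols <- setdiff(names(ext)[vapply(ext, is.numeric, logical(1))],
                         "position")
        em <- as.matrix(ext[eidx, ecols, drop = FALSE])
        colnames(em) <- paste(nm, ecols, sep = ".")
        x <- cbind(x, em)
    }
    rownames(x) <- NULL
    y <- if (target == "binary") labels$label else labels$CI
    FeatureTable(x, y, data.frame(position = labels$position))
}

#' Run the full pipeline on one chain
#'
#' Chains the stages: descriptors, criticality labels, dataset assembly,
#' the fixed filter cascade, GA descriptor selection and a leave-one-out
#' evaluation of the selected subset.  Deterministic for a given seed.
#'
#' @param chain a [ChainStructure-class] or PDB path.
#' @param muts mutagenesis data.frame or path.
#' @param msa optional alignment matrix or FASTA path.
#' @param external optional external descriptor tables (see
#'   [assembleDataset()]).
#' @param cutoff,atomMode contact definition.
#' @param spearmanThreshold redundancy-filter threshold.
#' @param control a [gaControl()].
#' @param seed integer seed governing every stochastic stage.
#' @param outDir optional directory for stage artifacts (descriptor CSV,
#'   label CSV, filter report JSON, GA report JSON).
#' @return list with `descriptors`, `labels`, `table` (filtered
#'   [FeatureTable-class]), `selection` (`gaSelection`), `evaluation`
#'   (`metricReport` of the selected subset under leave-one-out).
#' @export
runPipeline <- function(chain, muts, msa = NULL, external = list(),
                        cutoff = 5, atomMode = "heavy",
                        spearmanThreshold = 0.95, control = gaControl(),
                        seed = 1L, outDir = NULL) {
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    art <- function(f) if (is.null(outDir)) NULL else file.path(outDir, f)
    descriptors <- runDescriptors(chain, msa = msa, cutoff = cutoff,
                                  atomMode = atomMode,
                                  out = art("descriptors.csv"))
    labels <- runCriticalityLabels(muts, out = art("labels.csv"))
    ft <- assembleDataset(descriptors, labels, external = external)
    ft <- filterFeatures(ft, spearmanThreshold)
    if (!is.null(outDir)) writeFilterReport(ft, art("filter_report.json"))
    sel <- gaSelect(ft, control = control, seed = seed)
    if (!is.null(outDir)) writeGAReport(sel, art("ga_report.json"))
    spec <- classifierSpec(classWeights = control$classWeights,
                           cost = control$cost, positiveClass = "critical")
    sub <- ftKeepColumns(ft, sel$best$chromosome,
                         list(filter = "ga_selection",
                              removed = setdiff(descriptorNames(ft),
                                                sel$best$names)))
    evalRep <- leaveOneOut(sub, spec)
    list(descriptors = descriptors, labels = labels, table = ft,
         selection = sel, evaluation = evalRep, seed = seed)
}
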