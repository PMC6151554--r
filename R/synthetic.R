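## Synthetic fixtures: toy structures, alignments, mutagenesis tables and
## feature tables with planted signal.  Every generator is a pure function
## of its seed and emits the ground truth its output was built from, so the
## other modules' tests can assert against it directly.

#' Generate a toy chain structure
#'
#' Deterministic C-alpha traces with a known geometry: `"spiral"` places
#' residues on a helix-like spiral (radius 2.3 A, 100 degrees and 1.5 A
#' rise per residue, the approximate alpha-helical C-alpha geometry),
#' `"lattice"` on a straight line with fixed spacing (a 3.8 A-spaced line
#' under a 5 A cutoff gives a path graph), and `"coil"` on a random
#' self-avoiding-ish walk with 3.8 A steps.
#'
#' @param nResidues number of residues (>= 2).
#' @param geometry `"spiral"`, `"lattice"` or `"coil"`.
#' @param spacing step length in Angstrom for `"lattice"` / `"coil"`
#'   (default 3.8, the consecutive C-alpha distance).
#' @param sequence optional one-letter sequence (random under `seed` if
#'   missing).
#' @param seed RNG seed (used for the sequence and the coil walk).
#' @return A [ChainStructure-class] (chain `"A"`, one CA atom per residue).
#' @export
makeStructure <- function(nResidues, geometry = c("spiral", "lattice", "coil"),
                          spacing = 3.8, sequence = NULL, seed = 1L) {
    geometry <- match.arg(geometry)
    stopifnot(nResidues >= 2L)
    set.seed(seed)
    i <- seq_len(nResidues) - 1L
    coords <- switch(geometry,
        spiral = cbind(2.3 * cos(i * 100 * pi / 180),
                       2.3 * sin(i * 100 * pi / 180),
                       1.5 * i),
        lattice = cbind(spacing * i, 0, 0),
        coil = {
            xyz <- matrix(0, nResidues, 3L)
            for (k in seq.int(2L, nResidues)) {
                v <- stats::rnorm(3L)
                xyz[k, ] <- xyz[k - 1L, ] + spacing * v / sqrt(sum(v^2))
            }
            xyz
        })
    aa <- if (is.null(sequence)) sample(AA_CODES, nResidues, replace = TRUE)
          else strsplit(sequence, "")[[1L]]
    stopifnot(length(aa) == nResidues)
    residues <- data.frame(seqIndex = seq_len(nResidues),
                           resno = seq_len(nResidues), insert = "",
                           aa = aa, stringsAsFactors = FALSE)
    atoms <- data.frame(resIndex = seq_len(nResidues), name = "CA",
                        elem = "C", x = round(coords[, 1L], 3),
                        y = round(coords[, 2L], 3), z = round(coords[, 3L], 3),
                        stringsAsFactors = FALSE)
    new("ChainStructure", pdbID = paste0("synth_", geometry),
        chainID = "A", residues = residues, atoms = atoms)
}

#' Generate a toy multiple sequence alignment with known column frequencies
#'
#' Builds `nRows` homolog rows from a reference sequence: each homolog
#' position mutates independently with probability `subProb` to a uniformly
#' drawn different residue.  The realized per-column substitution fraction
#' (the ground-truth `S`) is returned alongside the alignment.
#'
#' @param reference one-letter reference sequence (character(1)), e.g.
#'   `chainSequence(chain)`.
#' @param nRows total rows including the reference (>= 2).
#' @param subProb per-position substitution probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param path optional FASTA output path.
#' @return list with `msa` (character matrix; row 1 = `"reference"`) and
#'   `S` (numeric vector of realized per-column substitution fractions).
#' @export
makeMSA <- function(reference, nRows = 10L, subProb = 0.3, seed = 1L,
                    path = NULL) {
    stopifnot(nRows >= 2L, subProb >= 0, subProb <= 1)
    set.seed(seed)
    ref <- strsplit(reference, "")[[1L]]
    L <- length(ref)
    msa <- matrix(rep(ref, each = nRows), nrow = nRows)
    for (r in seq.int(2L, nRows)) {
        hit <- stats::runif(L) < subProb
        if (any(hit))
            msa[r, hit] <- vapply(ref[hit], function(a)
                sample(setdiff(AA_CODES, a), 1L), character(1))
    }
    rownames(msa) <- c("reference", paste0("homolog", seq_len(nRows - 1L)))
    S <- vapply(seq_len(L), function(cl) mean(msa[-1L, cl] != ref[cl]),
                numeric(1))
    if (!is.null(path)) {
        seqs <- apply(msa, 1L, paste, collapse = "")
        writeLines(paste0(">", names(seqs), "\n", seqs), path)
    }
    list(msa = msa, S = S)
}

#' Generate a mutagenesis table hitting target criticality values
#'
#' For each position, searches over wild-type residues and small rank
#' subsets (all mutant phenotype) for a substitution set whose criticality
#' index is within `tolerance` of the target, and emits the records plus
#' the exact expected index, which the criticality module must reproduce.
#'
#' @param targetCI numeric vector of target indices in `(0, 1]`; names (or
#'   positions 1..k) become residue positions.
#' @param ranking a [SubstitutionRanking-class].
#' @param tolerance maximal |CI - target| (default 0.02).
#' @param maxM largest substitution-set size tried per position (default 3).
#' @param seed RNG seed (tie-breaking among equally good sets).
#' @return mutagenesis data.frame with attribute `expectedCI` (named
#'   numeric, the exact index of the emitted records per position).
#' @export
makeMutagenesis <- function(targetCI, ranking, tolerance = 0.02, maxM = 3L,
                            seed = 1L) {
    stopifnot(all(targetCI > 0), all(targetCI <= 1))
    set.seed(seed)
    tab <- rankingTable(ranking)
    positions <- if (is.null(names(targetCI))) seq_along(targetCI)
                 else as.integer(names(targetCI))
    ranksOf <- split(tab$rank, tab$from)
    rows <- list()
    expected <- numeric(length(targetCI))
    for (p in seq_along(targetCI)) {
        target <- targetCI[p]
        best <- NULL; bestErr <- Inf
        for (m in seq_len(maxM)) {
            denom <- topRankSum(m)
            for (wt in sample(AA_CODES)) {
                avail <- ranksOf[[wt]]
                sets <- utils::combn(avail, m)
                ci <- colSums(matrix(sets, nrow = m)) / denom
                err <- abs(ci - target)
                j <- which.min(err)
                if (err[j] < bestErr) {
                    bestErr <- err[j]
                    best <- list(wt = wt, ranks = sets[, j], ci = ci[j])
                }
            }
            if (bestErr <= tolerance) break
        }
        if (bestErr > tolerance)
            stop(sprintf("no substitution set within %.3f of target %.3f",
                         tolerance, target))
        sub <- tab[match(best$ranks, tab$rank), ]
        rows[[p]] <- data.frame(position = positions[p], wt = best$wt,
                                mut = sub$to, phenotype = "mutant",
                                stringsAsFactors = FALSE)
        expected[p] <- best$ci
    }
    out <- do.call(rbind, rows)
    attr(out, "expectedCI") <- stats::setNames(expected, positions)
    out
}

#' Generate a feature table with planted signal
#'
#' Informative descriptors are standard normal with a class-conditional
#' mean shift of `effectSize` for the critical class; noise descriptors are
#' class-independent standard normal.  Optionally, `nTwins` of the first
#' descriptors get a strictly monotone transformed copy (`x^3`), planted
#' redundancy for the Spearman filter.  Class imbalance defaults to 20
#' percent critical, the typical shape of curated mutagenesis datasets.
#'
#' @param nInstances number of rows (>= 20).
#' @param nInformative,nNoise descriptor counts.
#' @param classBalance fraction of critical instances (default 0.2).
#' @param effectSize class-conditional mean shift of informative
#'   descriptors (default 3).
#' @param nTwins number of monotone twin columns to plant (default 0).
#' @param seed RNG seed.
#' @return A [FeatureTable-class]; attributes `informative` and `twins`
#'   name the planted columns.
#' @export
makeFeatureTable <- function(nInstances = 200L, nInformative = 5L,
                             nNoise = 95L, classBalance = 0.2,
                             effectSize = 3, nTwins = 0L, seed = 1L) {
    stopifnot(nInstances >= 20L, classBalance > 0, classBalance < 1)
    set.seed(seed)
    nCrit <- max(1L, round(nInstances * classBalance))
    y <- factor(rep(c("critical", "non-critical"),
                    c(nCrit, nInstances - nCrit)),
                levels = c("critical", "non-critical"))
    y <- y[sample.int(nInstances)]
    inf <- matrix(stats::rnorm(nInstances * nInformative), nInstances) +
        effectSize * (y == "critical")
    noise <- matrix(stats::rnorm(nInstances * nNoise), nInstances)
    x <- cbind(inf, noise)
    colnames(x) <- c(sprintf("inf%02d", seq_len(nInformative)),
                     sprintf("noise%03d", seq_len(nNoise)))
    twins <- character()
    if (nTwins > 0L) {
        src <- colnames(x)[seq_len(min(nTwins, ncol(x)))]
        tw <- x[, src, drop = FALSE]^3
        colnames(tw) <- paste0(src, "_twin")
        x <- cbind(x, tw)
        twins <- colnames(tw)
    }
    ft <- FeatureTable(x, y, data.frame(protein = "synthetic",
                                        residue = seq_len(nInstances)))
    attr(ft, "informative") <- sprintf("inf%02d", seq_len(nInformative))
    attr(ft, "twins") <- twins
    ft
}
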