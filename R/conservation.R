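## Correlated-mutation index: per-column substitution frequencies from an
## MSA, summed over a residue's structural contacts.

GAP_CHARS <- c("-", ".")

#' Read a multiple sequence alignment
#'
#' @param path FASTA or Stockholm alignment file.
#' @param format `"fasta"` (default) or `"stockholm"`.
#' @return character matrix, one row per sequence (rownames = identifiers),
#'   one column per alignment column; residues upper-case, gaps as `-`.
#' @export
readMSA <- function(path, format = c("fasta", "stockholm")) {
    format <- match.arg(format)
    aln <- Biostrings::readAAMultipleAlignment(path, format = format)
    seqs <- as.character(Biostrings::unmasked(aln))
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
    m <- toupper(m)
    m[m %in% GAP_CHARS] <- "-"
    m
}

#' Map a chain's residues to alignment columns
#'
#' Selects the reference row (by identifier, or as the row whose ungapped
#' sequence best matches the chain sequence) and maps each residue to the
#' alignment column holding it.  More than 5 percent mismatch between the
#' chain sequence and the ungapped reference aborts, since a silently wrong
#' mapping would corrupt every correlated-mutation value.
#'
#' @param chain a [ChainStructure-class].
#' @param msa alignment matrix from [readMSA()].
#' @param refID optional rowname of the reference sequence; if `NULL` the
#'   best-matching row is used.
#' @param maxMismatch maximal tolerated mismatch fraction (default 0.05).
#' @return list with `refRow` (integer), `columns` (integer vector, length
#'   `nResidues(chain)`, alignment column of each residue).
#' @export
mapChainToAlignment <- function(chain, msa, refID = NULL, maxMismatch = 0.05) {
    seq <- strsplit(chainSequence(chain), "")[[1]]
    mismatchOf <- function(row) {
        cols <- which(!msa[row, ] %in% "-")
        if (length(cols) != length(seq)) return(Inf)
        mean(msa[row, cols] != seq)
    }
    if (!is.null(refID)) {
        refRow <- match(refID, rownames(msa))
        if (is.na(refRow)) stop("reference sequence not found: ", refID)
    } else {
        mm <- vapply(seq_len(nrow(msa)), mismatchOf, numeric(1))
        refRow <- which.min(mm)
    }
    mm <- mismatchOf(refRow)
    if (!is.finite(mm))
        stop("ungapped reference length does not match the chain (",
             sum(!msa[refRow, ] %in% "-"), " vs ", length(seq), " residues)")
    if (mm > maxMismatch)
        stop(sprintf(paste0("reference/chain mismatch %.1f%% exceeds %.1f%%; ",
                            "refusing to map"), 100 * mm, 100 * maxMismatch))
    list(refRow = refRow, columns = which(!msa[refRow, ] %in% "-"))
}

#' Substitution frequency of one alignment column
#'
#' The fraction of non-gap homologs (reference row excluded) whose residue
#' differs from the reference residue at that column: the observed
#' normalized frequency of residue substitutions, `S` in `[0, 1]`.
#'
#' @param msa alignment matrix from [readMSA()].
#' @param refRow reference row index.
#' @param column alignment column index.
#' @return numeric(1), `S`; 0 (with a warning) when no homolog covers the
#'   column.
#' @export
columnSubstitutionFrequency <- function(msa, refRow, column) {
    ref <- msa[refRow, column]
    if (ref %in% "-") stop("unaligned reference position: column ", column)
    others <- msa[-refRow, column]
    others <- others[!others %in% "-"]
    if (!length(others)) {
        warning("empty column ", column, ": S set to 0")
        return(0)
    }
    mean(others != ref)
}

#' Per-residue substitution frequencies
#'
#' @param chain a [ChainStructure-class].
#' @param msa alignment matrix from [readMSA()].
#' @param refID optional reference identifier (see [mapChainToAlignment()]).
#' @return data.frame with `seqIndex`, `column`, `S`.
#' @export
substitutionProfile <- function(chain, msa, refID = NULL) {
    map <- mapChainToAlignment(chain, msa, refID)
    S <- vapply(map$columns, function(cl)
        suppressWarnings(columnSubstitutionFrequency(msa, map$refRow, cl)),
        numeric(1))
    data.frame(seqIndex = seq_len(nResidues(chain)),
               column = map$columns, S = S)
}

#' Correlated-mutation index of every residue
#'
#' For residue `j` with `m` contacting residues, `CM_j` is the sum of the
#' substitution frequencies `S_i` of those contacts; residues without
#' contacts get `CM = 0`, and contacts without an aligned column contribute
#' 0 (with a warning).  Since each `S` lies in `[0, 1]`, `CM_j` is bounded
#' by the contact count of `j`.
#'
#' @param g a [ResidueContactGraph-class].
#' @param S numeric vector of per-residue substitution frequencies (indexed
#'   like the graph nodes); `NA` marks unaligned residues.
#' @return numeric vector of per-residue CM values.
#' @examples
#' g <- contactGraphFromEdges(3, rbind(c(1, 2), c(2, 3)))
#' correlatedMutationIndex(g, c(0.2, 0.5, 0.3))
#' @export
correlatedMutationIndex <- function(g, S) {
    if (length(S) != g@nNodes)
        stop("S must have one value per graph node")
    if (anyNA(S))
        warning("unaligned residues contribute S = 0 to their contacts")
    S0 <- ifelse(is.na(S), 0, S)
    vapply(seq_len(g@nNodes), function(j) {
        nb <- contactNeighbors(g, j)
        if (!length(nb)) 0 else sum(S0[nb])
    }, numeric(1))
}
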