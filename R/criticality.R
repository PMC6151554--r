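## Criticality index from site-directed mutagenesis tables.
##
## Every possible substitution between distinct standard amino acids is
## ranked by the Euclidean distance between the two residues' five
## physicochemical factor scores; rank 380 is the most dissimilar
## substitution.  A position's criticality index compares the ranks of its
## reported mutations with the largest attainable rank sum, so tolerated
## dissimilar substitutions pull the index down and deleterious ones push it
## up.

#' The five-factor amino-acid descriptor table
#'
#' Loads the packaged factor-analysis scores (polarity, secondary-structure
#' propensity, molecular volume, codon diversity, electrostatic charge; one
#' 5-vector per standard amino acid, Atchley et al. 2005).  Any complete
#' 20-row replacement table can be supplied to
#' [buildSubstitutionRanking()] instead.
#'
#' @param path optional path to a TSV with columns `aa` plus five numeric
#'   factors; defaults to the packaged table.
#' @return numeric 20 x 5 matrix, rownames = one-letter codes.
#' @export
aaFactorTable <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "aa_factors_atchley2005.tsv",
                            package = "critres")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$aa
    if (!setequal(rownames(m), AA_CODES) || nrow(m) != 20L)
        stop("factor table must cover exactly the 20 standard amino acids")
    if (ncol(m) != 5L) stop("factor table must have 5 factor columns")
    if (!all(is.finite(m))) stop("factor table contains non-finite values")
    m[AA_CODES, , drop = FALSE]
}

#' Rank all 380 substitutions by physicochemical dissimilarity
#'
#' Scores every ordered pair of distinct amino acids by the Euclidean
#' distance between their factor vectors (the 20 identity pairs among the
#' 400 ordered pairs are not mutations and are excluded), then ranks the 380
#' substitutions ascending by distance so that the most dissimilar mutations
#' receive the highest ranks.  Distance ties are broken by `(from, to)`
#' lexicographic order; ranks are therefore a gap-free permutation of
#' 1..380.
#'
#' @param factors 20 x 5 factor matrix from [aaFactorTable()].
#' @return A [SubstitutionRanking-class].
#' @examples
#' rk <- buildSubstitutionRanking(aaFactorTable())
#' head(rankingTable(rk))
#' @export
buildSubstitutionRanking <- function(factors = aaFactorTable()) {
    if (!is.matrix(factors) || nrow(factors) != 20L || ncol(factors) != 5L ||
        !setequal(rownames(factors), AA_CODES))
        stop("need a complete 20 x 5 factor table")
    pairs <- expand.grid(to = AA_CODES, from = AA_CODES,
                         stringsAsFactors = FALSE)[, c("from", "to")]
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
    d <- sqrt(rowSums((factors[pairs$from, , drop = FALSE] -
                       factors[pairs$to, , drop = FALSE])^2))
    ord <- order(d, pairs$from, pairs$to)
    tab <- data.frame(from = pairs$from[ord], to = pairs$to[ord],
                      distance = d[ord], rank = seq_len(380L),
                      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    new("SubstitutionRanking", table = tab)
}

#' Rank of specific substitutions
#'
#' @param ranking a [SubstitutionRanking-class].
#' @param from,to one-letter codes (vectorized).
#' @return integer vector of ranks in 1..380.
#' @export
substitutionRank <- function(ranking, from, to) {
    tab <- ranking@table
    idx <- match(paste(from, to), paste(tab$from, tab$to))
    if (anyNA(idx)) stop("unknown substitution: ",
                         paste(from[is.na(idx)], to[is.na(idx)], sep = "->",
                               collapse = ", "))
    as.integer(tab$rank[idx])
}

## Largest attainable sum of m ranks.  Default: the top-m ranks
## (381-m)..380.  strict = TRUE uses the literal m+1-term bound
## (380-m)..380, under which the index cannot reach 1.
topRankSum <- function(m, strict = FALSE) {
    lo <- if (strict) 380L - m else 381L - m
    sum(seq.int(lo, 380L))
}

#' Criticality index from substitution ranks
#'
#' The low-level arithmetic behind [annotateCriticality()].  For a position
#' whose reported mutations all produced a mutant (loss-of-function)
#' phenotype, `CI = sum(R_i) / topRankSum(m)` where the `R_i` are the
#' mutations' ranks and the denominator is the largest sum `m` ranks can
#' attain, so `CI` is in `(0, 1]` and reaches 1 exactly when the reported
#' mutations are the most dissimilar ones possible.  When both phenotypes
#' are reported at a position the two sets enter with opposite signs:
#' `CI = ((1 - sum(RW)/D_w) + sum(RM)/D_m) / 2`, with `D_w`, `D_m` the
#' corresponding top-rank sums.  Positions where only wild-type phenotypes
#' were observed are scored by the tolerance term alone,
#' `CI = 1 - sum(RW)/D_w`.
#'
#' @param ranksMutant integer ranks of mutations with a mutant phenotype
#'   (may be empty).
#' @param ranksWildType integer ranks of mutations with a wild-type
#'   phenotype (may be empty).
#' @param strict use the literal `m+1`-term denominator bound instead of the
#'   top-`m` sum (default `FALSE`; under `strict = TRUE` the index cannot
#'   reach 1).
#' @return numeric(1), the criticality index.
#' @examples
#' ciFromRanks(380)                      # single, maximally dissimilar: 1
#' ciFromRanks(c(100, 200, 300))         # 600 / (378+379+380)
#' ciFromRanks(380, ranksWildType = 380) # mixed evidence: 0.5
#' @export
ciFromRanks <- function(ranksMutant, ranksWildType = integer(), strict = FALSE) {
    mm <- length(ranksMutant)
    mw <- length(ranksWildType)
    if (mm + mw == 0L) stop("no data: position has no reported mutations")
    if (mm && (any(ranksMutant < 1L) || any(ranksMutant > 380L)) ||
        mw && (any(ranksWildType < 1L) || any(ranksWildType > 380L)))
        stop("ranks must lie in 1..380")
    if (mw == 0L)
        return(sum(ranksMutant) / topRankSum(mm, strict))
    wtTerm <- 1 - sum(ranksWildType) / topRankSum(mw, strict)
    if (mm == 0L) return(wtTerm)
    (wtTerm + sum(ranksMutant) / topRankSum(mm, strict)) / 2
}

#' Read a site-directed mutagenesis table
#'
#' Expects a CSV/TSV with header columns `position`, `wt`, `mut`,
#' `phenotype`.  Phenotypes must be binary; the spellings `wild-type`,
#' `wild_type`, `wildtype`, `wt` normalize to `wild-type`, and `mutant`,
#' `mut` to `mutant`.  Intermediate phenotypes are rejected.
#'
#' @param path file path; the separator is inferred from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @return validated data.frame with columns `position` (integer), `wt`,
#'   `mut` (one-letter codes), `phenotype`.
#' @export
readMutagenesis <- function(path) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    validateMutagenesis(tab)
}

## Normalize and validate a mutagenesis data.frame.
validateMutagenesis <- function(tab) {
    need <- c("position", "wt", "mut", "phenotype")
    if (!all(need %in% names(tab)))
        stop("mutagenesis table needs columns ", paste(need, collapse = ", "))
    tab$wt <- toupper(tab$wt)
    tab$mut <- toupper(tab$mut)
    ph <- tolower(gsub("[_ ]", "-", trimws(tab$phenotype)))
    ph[ph %in% c("wild-type", "wildtype", "wt")] <- "wild-type"
    ph[ph %in% c("mutant", "mut")] <- "mutant"
    bad <- setdiff(unique(ph), c("wild-type", "mutant"))
    if (length(bad))
        stop("phenotype must be 'wild-type' or 'mutant'; found: ",
             paste(bad, collapse = ", "))
    tab$phenotype <- ph
    if (!all(tab$wt %in% AA_CODES) || !all(tab$mut %in% AA_CODES))
        stop("wt/mut must be standard one-letter amino-acid codes")
    if (any(tab$wt == tab$mut))
        stop("wt and mut must differ (identity pairs are not mutations)")
    if (any(tab$position != as.integer(tab$position)))
        stop("positions must be integers")
    tab$position <- as.integer(tab$position)
    tab[, need]
}

#' Score positions with the criticality index
#'
#' Collapses duplicate reports of the same substitution at a position
#' (conflicting phenotype duplicates are kept as one wild-type and one
#' mutant entry, which routes the position to the mixed-evidence formula),
#' computes each covered position's criticality index and the binary label
#' (`critical` iff `CI > 0.5`).  Positions absent from the table are not
#' scored.
#'
#' @param muts mutagenesis data.frame (see [readMutagenesis()]).
#' @param ranking a [SubstitutionRanking-class].
#' @param strict passed to [ciFromRanks()].
#' @return data.frame with one row per covered position: `position`, `m`
#'   (number of distinct reported mutations), `CI`, `label`.
#' @examples
#' rk <- buildSubstitutionRanking()
#' tab <- data.frame(position = c(5, 5, 9), wt = c("A", "A", "L"),
#'                   mut = c("W", "D", "I"),
#'                   phenotype = c("mutant", "mutant", "wild-type"))
#' annotateCriticality(tab, rk)
#' @export
annotateCriticality <- function(muts, ranking, strict = FALSE) {
    muts <- validateMutagenesis(muts)
    if (!nrow(muts)) stop("empty mutagenesis table")
    muts <- unique(muts)
    out <- lapply(split(muts, muts$position), function(d) {
        wtAA <- unique(d$wt)
        if (length(wtAA) > 1L)
            stop("position ", d$position[1],
                 " reported with conflicting wild-type residues: ",
                 paste(wtAA, collapse = ", "))
        r <- substitutionRank(ranking, d$wt, d$mut)
        isMut <- d$phenotype == "mutant"
        data.frame(position = d$position[1],
                   m = nrow(d),
                   CI = ciFromRanks(r[isMut], r[!isMut], strict = strict))
    })
    out <- do.call(rbind, out)
    out <- out[order(out$position), , drop = FALSE]
    rownames(out) <- NULL
    out$label <- binarizeCI(out$CI)
    out
}

#' Binary critical / non-critical labels from CI values
#'
#' Threshold exactly 0.5: `CI > 0.5` is critical, `CI <= 0.5` non-critical.
#'
#' @param ci numeric vector of criticality-index values in `[0, 1]`.
#' @return factor with levels `critical`, `non-critical`.
#' @export
binarizeCI <- function(ci) {
    stopifnot(all(ci >= 0 & ci <= 1))
    factor(ifelse(ci > 0.5, "critical", "non-critical"),
           levels = c("critical", "non-critical"))
}
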