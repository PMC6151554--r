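## PDB ingestion: one chain, standard residues, heavy atoms only.

## Three-letter -> one-letter codes, plus common modified residues mapped to
## their parent amino acid so contact graphs stay on the 20-letter alphabet.
AA3TO1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
            GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
            MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
            SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y",
            ## modified residues -> parent
            MSE = "M", SEC = "C", CSO = "C", SEP = "S", TPO = "T",
            PTR = "Y", HYP = "P", MLY = "K", PCA = "Q")

#' Read one chain of a PDB file
#'
#' Parses a PDB file (plain or gzip-compressed), selects one chain of one
#' model and returns its standard amino-acid residues with heavy-atom
#' coordinates.  Hydrogens and waters are excluded; alternate locations are
#' resolved to the highest-occupancy conformer (ties go to the first one in
#' the file); common modified residues (e.g. selenomethionine) are mapped to
#' their parent amino acid, and any remaining non-standard polymer residues
#' are skipped with a warning.
#'
#' @param path path to a PDB file (`.pdb` or `.pdb.gz`).
#' @param chainID chain identifier to extract (default `"A"`).
#' @param model model number for multi-model files (default 1; crystal
#'   structures have a single model).
#' @return A [ChainStructure-class] object.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeChainPDB(makeStructure(10, seed = 1), pdb)
#' ch <- readChain(pdb, "A")
#' nResidues(ch)
#' @export
readChain <- function(path, chainID = "A", model = 1L) {
    if (!file.exists(path)) stop("cannot read PDB file: ", path)
    pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                    verbose = FALSE),
                    error = function(e) stop("PDB parse error in '", path,
                                             "': ", conditionMessage(e)))
    atoms <- pdb$atom
    if (model != 1L)
        warning("only model 1 is read; requested model ", model, " ignored")
    if (!chainID %in% unique(atoms$chain))
        stop("chain not found: '", chainID, "' in ", path)
    atoms <- atoms[atoms$chain == chainID, , drop = FALSE]
    ## standard + mapped residues only (drops waters, ligands, ions)
    known <- atoms$resid %in% names(AA3TO1)
    skipped <- setdiff(unique(atoms$resid[!known]), "HOH")
    if (length(skipped))
        warning("skipping non-standard residues in chain ", chainID, ": ",
                paste(skipped, collapse = ", "))
    atoms <- atoms[known, , drop = FALSE]
    ## drop hydrogens by element symbol (fall back to atom-name heuristics)
    elem <- toupper(trimws(ifelse(is.na(atoms$elesy) | atoms$elesy == "",
                                  substr(gsub("^[0-9]+", "", atoms$elety), 1, 1),
                                  atoms$elesy)))
    atoms <- atoms[!elem %in% c("H", "D"), , drop = FALSE]
    elem <- elem[!elem %in% c("H", "D")]
    if (nrow(atoms) == 0L) stop("empty chain: no standard residues in chain ",
                                chainID)
    ## resolve altlocs: per (residue, atom name) keep highest occupancy,
    ## ties -> first occurrence in file order
    ins <- ifelse(is.na(atoms$insert), "", atoms$insert)
    key <- paste(atoms$resno, ins, atoms$elety, sep = "\r")
    occ <- ifelse(is.na(atoms$o), 1, atoms$o)
    ord <- order(factor(key, levels = unique(key)), -occ,
                 seq_len(nrow(atoms)))
    first <- !duplicated(key[ord])
    keep <- sort(ord[first])
    atoms <- atoms[keep, , drop = FALSE]
    elem <- elem[keep]
    ins <- ins[keep]

    reskey <- paste(atoms$resno, ins, sep = "\r")
    resLevels <- unique(reskey)
    resIndex <- match(reskey, resLevels)
    firstRow <- match(resLevels, reskey)
    residues <- data.frame(seqIndex = seq_along(resLevels),
                           resno = atoms$resno[firstRow],
                           insert = ins[firstRow],
                           aa = unname(AA3TO1[atoms$resid[firstRow]]),
                           stringsAsFactors = FALSE)
    if (any(diff(residues$resno) < 0))
        warning("PDB residue numbering is not increasing in chain ", chainID)
    atomTab <- data.frame(resIndex = resIndex,
                          name = trimws(atoms$elety),
                          elem = elem,
                          x = atoms$x, y = atoms$y, z = atoms$z,
                          stringsAsFactors = FALSE)
    id <- sub("\\.pdb(\\.gz)?$", "", basename(path), ignore.case = TRUE)
    new("ChainStructure", pdbID = id, chainID = chainID,
        residues = residues, atoms = atomTab)
}

#' Write a ChainStructure as a PDB file
#'
#' Emits standard `ATOM` records (occupancy 1.00, B-factor 0.00).  Writing
#' and re-reading a chain reproduces residues, atom names and coordinates to
#' the PDB format's 0.001-Angstrom precision.
#'
#' @param chain a [ChainStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeChainPDB <- function(chain, path) {
    res <- chain@residues
    atm <- chain@atoms
    aa1to3 <- names(AA3TO1)[match(res$aa, AA3TO1)]   # first (canonical) match
    aa1to3[is.na(aa1to3)] <- "UNK"
    lines <- character(nrow(atm))
    for (k in seq_len(nrow(atm))) {
        i <- atm$resIndex[k]
        name <- atm$name[k]
        namef <- if (nchar(name) >= 4L) substr(name, 1, 4) else
            sprintf(" %-3s", name)
        lines[k] <- sprintf(
            "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            k, namef, aa1to3[i], chain@chainID, res$resno[i],
            ifelse(res$insert[i] == "", " ", res$insert[i]),
            atm$x[k], atm$y[k], atm$z[k], 1, 0, atm$elem[k])
    }
    writeLines(c(lines, "END"), path)
    invisible(path)
}

#' Serialize a ChainStructure to JSON
#'
#' Debug/interchange helper; the JSON mirrors the residue and atom tables.
#'
#' @param chain a [ChainStructure-class].
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
chainToJSON <- function(chain, path = NULL) {
    obj <- list(pdbID = chain@pdbID, chainID = chain@chainID,
                residues = chain@residues, atoms = chain@atoms)
    js <- jsonlite::toJSON(obj, dataframe = "columns", digits = NA,
                           auto_unbox = TRUE)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}
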