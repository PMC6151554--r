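# Hand-written PDB fixture text used by the structure-io tests.

pdbLine <- function(serial, name, alt, resid, chain, resno, x, y, z,
                    occ = 1, elem = "C", record = "ATOM  ") {
    sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, sprintf(" %-3s", name), alt, resid, chain, resno,
            x, y, z, occ, 0, elem)
}

# Three alanines in chain A plus one glycine in chain B.
writeToyPDB <- function(path) {
    writeLines(c(
        pdbLine(1, "N",  " ", "ALA", "A", 1, 0.0, 0.0, 0.0, elem = "N"),
        pdbLine(2, "CA", " ", "ALA", "A", 1, 1.5, 0.0, 0.0),
        pdbLine(3, "CA", " ", "ALA", "A", 2, 5.3, 0.0, 0.0),
        pdbLine(4, "CA", " ", "ALA", "A", 3, 9.1, 0.0, 0.0),
        pdbLine(5, "CA", " ", "GLY", "B", 1, 0.0, 5.0, 0.0),
        "END"), path)
    path
}

# One residue with an altloc pair (A occupancy 0.6, B occupancy 0.4), an MSE
# HETATM residue, a hydrogen and a water.
writeTrickyPDB <- function(path) {
    writeLines(c(
        pdbLine(1, "CA", "A", "LYS", "A", 1, 1.000, 0.0, 0.0, occ = 0.6),
        pdbLine(2, "CA", "B", "LYS", "A", 1, 2.000, 0.0, 0.0, occ = 0.4),
        pdbLine(3, "H",  " ", "LYS", "A", 1, 1.100, 1.0, 0.0, elem = "H"),
        pdbLine(4, "CA", " ", "MSE", "A", 2, 4.800, 0.0, 0.0,
                record = "HETATM"),
        pdbLine(5, "SE", " ", "MSE", "A", 2, 5.900, 1.0, 0.0, elem = "SE",
                record = "HETATM"),
        pdbLine(6, "O",  " ", "HOH", "A", 101, 9.0, 9.0, 9.0, elem = "O",
                record = "HETATM"),
        "END"), path)
    path
}
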