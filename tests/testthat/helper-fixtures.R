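# In-code PDB fixtures and small structure builders for the tests.

fixture_path <- function(name) {
  system.file("extdata", name, package = "contactpot", mustWork = TRUE)
}

write_pdb_text <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
          serial, name, alt, resid, chain, resno, x, y, z, occ, element)
}

hetatm_only_pdb <- function() {
  write_pdb_text(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END"))
}

three_model_pdb <- function() {
  mk <- function(off) c(
    pdb_atom_line(1, "N", "GLY", "A", 1, off, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, off + 1.458, 0, 0),
    pdb_atom_line(3, "C", "GLY", "A", 1, off + 2.0, 1.4, 0),
    pdb_atom_line(4, "O", "GLY", "A", 1, off + 1.7, 2.2, 0.9))
  write_pdb_text(c("MODEL        1", mk(0), "ENDMDL",
                   "MODEL        2", mk(50), "ENDMDL",
                   "MODEL        3", mk(100), "ENDMDL", "END"))
}

altloc_pdb <- function() {
  write_pdb_text(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(3, "CA", "ALA", "A", 1, 1.500, 0.1, 0, occ = 0.6, alt = "B"),
    pdb_atom_line(4, "C", "ALA", "A", 1, 2.0, 1.4, 0),
    pdb_atom_line(5, "O", "ALA", "A", 1, 1.7, 2.2, 0.9),
    pdb_atom_line(6, "CB", "ALA", "A", 1, 2.0, -0.8, 1.2, occ = 0.5, alt = "A"),
    pdb_atom_line(7, "CB", "ALA", "A", 1, 2.1, -0.7, 1.3, occ = 0.5, alt = "B"),
    "END"))
}

gap_numbering_pdb <- function() {
  res <- function(serial0, resno, x0) c(
    pdb_atom_line(serial0 + 1, "N", "GLY", "A", resno, x0, 0, 0),
    pdb_atom_line(serial0 + 2, "CA", "GLY", "A", resno, x0 + 1.458, 0, 0),
    pdb_atom_line(serial0 + 3, "C", "GLY", "A", resno, x0 + 2.0, 1.4, 0),
    pdb_atom_line(serial0 + 4, "O", "GLY", "A", resno, x0 + 1.7, 2.2, 0.9))
  write_pdb_text(c(res(0, 1, 0), res(4, 5, 4), res(8, 6, 8), "END"))
}

# three-letter -> one-letter lookup for the helper below
AA1_OF <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# synthetic structure built directly from an atom table, with metadata;
# used for curation tests where PDB headers would be cumbersome.
# `residues` is a named list: names are 3-letter codes, values the atom
# names present.
fake_structure <- function(id, residues, resolution = NA, method = NA) {
  rows <- list()
  serial <- 0
  for (i in seq_along(residues)) {
    resid <- names(residues)[i]
    for (nm in residues[[i]]) {
      serial <- serial + 1
      rows[[serial]] <- data.frame(
        chain = "A", resno = i, res_index = i, resid = resid,
        aa = unname(AA1_OF[resid]),
        elety = nm, elesy = substr(gsub("[0-9]", "", nm), 1, 1),
        x = serial * 4, y = 0, z = 0, radius = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  s <- list(id = id, atoms = do.call(rbind, rows),
            resolution = resolution, method = method)
  class(s) <- "contactpot_structure"
  s
}

backbone_atoms <- c("N", "CA", "C", "O")
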