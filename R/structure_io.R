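# PDB input/output and training-set curation.
#
# Internal structure model: a list with
#   id         - structure identifier (file basename by default)
#   atoms      - data.frame(chain, resno, res_index, resid, aa, elety,
#                elesy, x, y, z, radius) with one row per heavy atom;
#                res_index counts residues consecutively within each chain
#                in file order, so author numbering gaps and insertion
#                codes do not inflate sequence separations
#   resolution - Angstrom, NA when the header carries none
#   method     - experiment method string, NA when absent

new_structure <- function(id, atoms, resolution = NA_real_,
                          method = NA_character_) {
  obj <- list(id = id, atoms = atoms, resolution = resolution,
              method = method)
  class(obj) <- "contactpot_structure"
  obj
}

#' @export
print.contactpot_structure <- function(x, ...) {
  cat(sprintf("<contactpot_structure> %s: %d residues, %d heavy atoms",
              x$id, length(unique(paste(x$atoms$chain, x$atoms$res_index))),
              nrow(x$atoms)))
  if (!is.na(x$resolution)) cat(sprintf(", %.2f A", x$resolution))
  cat("\n")
  invisible(x)
}

#' Number of residues in a structure
#' @param structure A `contactpot_structure`.
#' @return Integer residue count (over all chains).
#' @export
n_residues <- function(structure) {
  length(unique(paste(structure$atoms$chain, structure$atoms$res_index)))
}

# scan a PDB header for resolution (REMARK 2) and experiment (EXPDTA)
.parse_pdb_header <- function(path) {
  lines <- readLines(path, n = 500L, warn = FALSE)
  res <- NA_real_
  meth <- NA_character_
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl)) {
    tail_part <- sub(".*RESOLUTION\\.?", "", rl[1])
    m <- regmatches(tail_part, regexpr("[0-9]+\\.?[0-9]*", tail_part))
    if (length(m)) res <- as.numeric(m)
  }
  el <- grep("^EXPDTA", lines, value = TRUE)
  if (length(el)) meth <- trimws(sub("^EXPDTA", "", el[1]))
  list(resolution = res, method = meth)
}

# infer hydrogen status from a PDB atom name when the element column is
# blank: strip leading digits, first remaining letter H or D
.is_hydrogen <- function(elety, elesy) {
  ifelse(!is.na(elesy) & nzchar(elesy),
         toupper(elesy) %in% c("H", "D"),
         substr(sub("^[0-9]*", "", elety), 1L, 1L) %in% c("H", "D"))
}

#' Read a PDB file into the internal structure model
#'
#' Keeps heavy atoms of standard amino-acid residues only: hydrogens,
#' HETATM records (including waters) and non-standard residues are
#' dropped.  For multi-model files only the first MODEL is used.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties favour altloc `A`).  Residues are renumbered consecutively per
#' chain in file order (`res_index`), so sequence separations are counts
#' of positions, not author-numbering differences.  Resolution and
#' experiment method are parsed from `REMARK   2` / `EXPDTA` when present.
#'
#' @param path Path to a PDB-format file.
#' @param id Structure identifier; defaults to the file basename.
#' @return A `contactpot_structure` (atom radii unset; see
#'   [assign_radii()]).
#' @export
parse_pdb <- function(path, id = sub("\\.(pdb|ent)$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, rm.insert = FALSE,
                    verbose = FALSE),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  hdr <- .parse_pdb_header(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% AA3, , drop = FALSE]
  if (nrow(at)) {
    at <- at[!.is_hydrogen(at$elety, at$elesy), , drop = FALSE]
  }
  if (nrow(at) == 0L) {
    stop("no standard-residue heavy atoms in '", path, "'")
  }
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc: keep the highest-occupancy conformer per (chain, residue, atom)
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(akey)) {
    alt <- at$alt
    alt[is.na(alt)] <- ""
    ord <- order(akey, -at$o, alt != "A", seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE][!duplicated(sort(akey)), , drop = FALSE]
    # restore file order
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }

  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  res_uid <- match(rkey, unique(rkey))            # residue order in file
  # consecutive index within each chain
  first <- !duplicated(res_uid)
  chain_of_res <- at$chain[first]
  res_index_of <- stats::ave(seq_along(chain_of_res), chain_of_res,
                             FUN = seq_along)
  atoms <- data.frame(
    chain = at$chain,
    resno = at$resno,
    res_index = res_index_of[res_uid],
    resid = at$resid,
    aa = aa_three_to_one(at$resid),
    elety = at$elety,
    elesy = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                   substr(sub("^[0-9]*", "", at$elety), 1L, 1L), at$elesy),
    x = at$x, y = at$y, z = at$z,
    radius = NA_real_,
    stringsAsFactors = FALSE)
  new_structure(id, atoms, hdr$resolution, hdr$method)
}

#' Write a structure to a PDB file
#'
#' @param structure A `contactpot_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$res_index, chain = at$chain, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   elesy = at$elesy)
  invisible(path)
}

# expected side-chain heavy atoms per residue type (backbone N CA C O
# is expected for all types; OXT is tolerated as a terminal extra)
EXPECTED_SIDECHAIN <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2"))

#' Check that every residue carries its full complement of heavy atoms
#'
#' @param structure A `contactpot_structure`.
#' @return TRUE when every residue has backbone N/CA/C/O plus all
#'   side-chain heavy atoms expected for its type.
#' @export
has_complete_side_chains <- function(structure) {
  at <- structure$atoms
  ruid <- paste(at$chain, at$res_index)
  for (u in unique(ruid)) {
    rows <- at[ruid == u, , drop = FALSE]
    expected <- c("N", "CA", "C", "O", EXPECTED_SIDECHAIN[[rows$resid[1]]])
    if (!all(expected %in% rows$elety)) return(FALSE)
  }
  TRUE
}

#' Apply training-set curation filters
#'
#' Retains structures that (i) report a crystallographic resolution of at
#' most `max_resolution` Angstrom, (ii) are not NMR structures, and
#' (iii) have complete heavy-atom side chains for every residue.
#' Structures with no recorded resolution fail filter (i).
#'
#' @param structures List of `contactpot_structure`.
#' @param max_resolution Resolution cutoff in Angstrom (default 2.5).
#' @param check_side_chains Set FALSE to skip the completeness check
#'   (useful for reduced-representation synthetic structures).
#' @return The retained subset, in input order.
#' @export
curate_training_set <- function(structures, max_resolution = 2.5,
                                check_side_chains = TRUE) {
  keep <- vapply(structures, function(s) {
    if (is.na(s$resolution) || s$resolution > max_resolution) return(FALSE)
    if (!is.na(s$method) && grepl("NMR", toupper(s$method))) return(FALSE)
    if (check_side_chains && !has_complete_side_chains(s)) return(FALSE)
    TRUE
  }, logical(1))
  structures[keep]
}
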