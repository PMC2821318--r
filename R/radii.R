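# Van der Waals group radii (heavy atoms only; hydrogens are absorbed
# into the group radius of their parent atom).

.contactpot_env <- new.env(parent = emptyenv())

# residues whose ring carbons take the aromatic group radius
AROMATIC_RESIDUES <- c("PHE", "TYR", "TRP", "HIS")

#' Van der Waals group-radius table
#'
#' Reads the packaged group-radius table.  Rows are keyed by
#' `residue_context` (`"*"` for any residue, `"aromatic"` for ring carbons
#' of PHE/TYR/TRP/HIS, `"wildcard"` for element-level fallbacks written as
#' `"C**"`, `"O**"`, `"S**"`, `"F**"`) and `atom_name` (PDB atom name).
#'
#' @param path Optional path to an alternative TSV with columns
#'   `residue_context`, `atom_name`, `radius_A`.
#' @return A data.frame with columns `residue_context`, `atom_name`,
#'   `radius_A`.
#' @export
vdw_radius_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.contactpot_env$radius_table)) {
      return(.contactpot_env$radius_table)
    }
    path <- system.file("extdata", "vdw_radii.tsv", package = "contactpot",
                        mustWork = TRUE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("residue_context", "atom_name", "radius_A") %in% names(tab)))
  if (any(tab$radius_A <= 0)) stop("radius table contains non-positive radii")
  .contactpot_env$radius_table <- tab
  tab
}

# radius for a single (residue, atom-name) pair; NA when no rule applies
.lookup_radius <- function(resid, elety, tab) {
  if (resid %in% AROMATIC_RESIDUES) {
    hit <- tab$radius_A[tab$residue_context == "aromatic" &
                          tab$atom_name == elety]
    if (length(hit)) return(hit[1L])
  }
  hit <- tab$radius_A[tab$residue_context == "*" & tab$atom_name == elety]
  if (length(hit)) return(hit[1L])
  wild <- paste0(substr(elety, 1L, 1L), "**")
  hit <- tab$radius_A[tab$residue_context == "wildcard" &
                        tab$atom_name == wild]
  if (length(hit)) return(hit[1L])
  NA_real_
}

#' Assign Van der Waals group radii to every atom of a structure
#'
#' Sets the `radius` column of the structure's atom table from the group
#' radius rules: backbone carbonyl `C` is 1.5 A, nitrogens 1.55 A,
#' oxygens 1.4 A (1.44 A for names matched only by the `O**` wildcard,
#' e.g. `OXT`), sulfurs 2.0 A, aromatic ring carbons of PHE/TYR/TRP/HIS
#' 1.75 A, and all other (aliphatic) carbons 2.0 A.  Atom names listed
#' with two radii (`CD1`, `CD2`, `CG`, `CZ`, ...) are resolved by residue
#' context: the 1.75 A value applies in aromatic residues, 2.0 A
#' elsewhere (so LEU `CD1` is 2.0 A but PHE `CD1` is 1.75 A).
#'
#' @param structure A `contactpot_structure` from [parse_pdb()] or
#'   [make_toy_structure()].
#' @param radius_table Radius table as returned by [vdw_radius_table()].
#' @return The structure with all `radius` entries set.
#' @export
assign_radii <- function(structure, radius_table = vdw_radius_table()) {
  stopifnot(inherits(structure, "contactpot_structure"))
  at <- structure$atoms
  key <- paste(at$resid, at$elety)
  ukey <- !duplicated(key)
  rmap <- mapply(.lookup_radius, at$resid[ukey], at$elety[ukey],
                 MoreArgs = list(tab = radius_table))
  names(rmap) <- key[ukey]
  rad <- unname(rmap[key])
  if (anyNA(rad)) {
    bad <- unique(key[is.na(rad)])
    stop("no Van der Waals radius rule for atom(s): ",
         paste(bad, collapse = ", "))
  }
  structure$atoms$radius <- rad
  structure
}
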