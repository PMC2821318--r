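# Pairwise residue contact areas by probe-sphere point sampling.
#
# For each atom A, quasi-uniform sample points are placed on the sphere
# of radius Ra+Rp centred at A (the locus of probe centres touching A).
# A point is in contact with atom B when it lies within Rb+Rp of B's
# centre; each point carries an equal share (Ra+Rp)^2 * 4*pi / n of the
# sphere area, and is credited once, to the nearest contacting partner
# atom.  Two atoms can be in contact at all only when their centre
# distance is at most Ra+Rb+2*Rp (overlapping probe-expanded spheres).

# probe radii the potential is tabulated for
SUPPORTED_PROBE_RADII <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 2.5)

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Generates `n` directions by the golden-spiral (Fibonacci) lattice.
#' Each point represents an equal area share, so the per-point weight on
#' a sphere of radius R is `R^2 * 4 * pi / n` and the weights sum to the
#' full sphere area exactly.
#'
#' @param n Number of points (at least 16).
#' @return An object of class `sphere_points`: list with `n`,
#'   `directions` (n x 3 matrix of unit vectors) and `point_weight(R)`.
#' @export
generate_sphere_points <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 16L) stop("n must be an integer >= 16")
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- pi * (3 - sqrt(5)) * i
  dirs <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  obj <- list(n = n, directions = dirs,
              point_weight = function(R) R^2 * 4 * pi / n)
  class(obj) <- "sphere_points"
  obj
}

#' Are two atoms in contact for a given probe radius?
#'
#' @param coord_a,coord_b Length-3 coordinate vectors, Angstrom.
#' @param radius_a,radius_b Van der Waals radii, Angstrom.
#' @param probe_radius Probe sphere radius Rp, Angstrom.
#' @return TRUE when the centre distance is at most
#'   `radius_a + radius_b + 2 * probe_radius`.
#' @export
atoms_in_contact <- function(coord_a, coord_b, radius_a, radius_b,
                             probe_radius) {
  sqrt(sum((coord_a - coord_b)^2)) <=
    radius_a + radius_b + 2 * probe_radius
}

#' Directed contact area of one atom onto a set of partner atoms
#'
#' Places sample points on the probe-expanded sphere of `atom_a` and
#' credits each point in contact with at least one partner to its nearest
#' contacting partner (ties go to the lowest partner index).  Occlusion
#' by third atoms is not modelled.
#'
#' @param coord_a Length-3 centre of the reference atom.
#' @param radius_a Its Van der Waals radius, Angstrom.
#' @param partner_coords m x 3 matrix of partner centres.
#' @param partner_radii Length-m vector of partner radii.
#' @param probe_radius Probe radius Rp, Angstrom.
#' @param points A `sphere_points` set.
#' @return Length-m vector of directed contact areas in square Angstrom;
#'   their sum never exceeds the full sphere area `4*pi*(Ra+Rp)^2`.
#' @export
atom_pair_contact_area <- function(coord_a, radius_a, partner_coords,
                                   partner_radii, probe_radius, points) {
  partner_coords <- matrix(partner_coords, ncol = 3L)
  m <- nrow(partner_coords)
  R1 <- radius_a + probe_radius
  w <- points$point_weight(R1)
  # sample points in absolute coordinates: n x 3
  P <- points$directions * R1
  P <- sweep(P, 2L, coord_a, "+")
  # squared distances from every point to every partner: n x m
  pp2 <- rowSums(P^2)
  b2 <- rowSums(partner_coords^2)
  D2 <- outer(pp2, b2, "+") - 2 * P %*% t(partner_coords)
  lim2 <- (partner_radii + probe_radius)^2
  D2[D2 > rep(lim2, each = points$n)] <- Inf      # mask non-contacting
  nearest <- max.col(-D2, ties.method = "first")
  hit <- is.finite(D2[cbind(seq_len(points$n), nearest)])
  counts <- tabulate(nearest[hit], nbins = m)
  counts * w
}

# all directed area from the atoms of residue rows `ai` onto residue
# rows `aj` of an atom table; returns a single total in A^2
.directed_residue_area <- function(at, ai, aj, probe_radius, points) {
  cj <- as.matrix(at[aj, c("x", "y", "z")])
  rj <- at$radius[aj]
  total <- 0
  for (k in ai) {
    ck <- c(at$x[k], at$y[k], at$z[k])
    # prefilter partners by the contact criterion
    d2 <- (cj[, 1] - ck[1])^2 + (cj[, 2] - ck[2])^2 + (cj[, 3] - ck[3])^2
    sel <- d2 <= (at$radius[k] + rj + 2 * probe_radius)^2
    if (!any(sel)) next
    a <- atom_pair_contact_area(ck, at$radius[k],
                                cj[sel, , drop = FALSE], rj[sel],
                                probe_radius, points)
    total <- total + sum(a)
  }
  total
}

#' Contact area between two residues
#'
#' Symmetric by construction: the mean of the two directed sums (points
#' of residue i credited to atoms of residue j, and vice versa).  Each
#' sample point is counted at most once toward the partner residue even
#' when it contacts several of its atoms.  Backbone-backbone contacts are
#' included.
#'
#' @param structure A `contactpot_structure` with radii assigned.
#' @param res_i,res_j Residue selectors: `c(chain, res_index)` or a
#'   plain res_index (single-chain structures).
#' @param probe_radius Probe radius Rp, Angstrom.
#' @param points A `sphere_points` set.
#' @return Contact area in square Angstrom (>= 0).
#' @export
residue_pair_contact_area <- function(structure, res_i, res_j,
                                      probe_radius,
                                      points = generate_sphere_points(1024)) {
  at <- structure$atoms
  if (anyNA(at$radius)) stop("assign_radii() must be run first")
  sel <- function(r) {
    if (length(r) == 2L) which(at$chain == r[1] & at$res_index == as.integer(r[2]))
    else which(at$res_index == as.integer(r))
  }
  ai <- sel(res_i); aj <- sel(res_j)
  if (!length(ai) || !length(aj)) stop("residue selector matched no atoms")
  if (identical(sort(ai), sort(aj))) stop("res_i and res_j must differ")
  a_ij <- .directed_residue_area(at, ai, aj, probe_radius, points)
  a_ji <- .directed_residue_area(at, aj, ai, probe_radius, points)
  (a_ij + a_ji) / 2
}

#' Map sequence separations to separation bins
#'
#' Default binning: separations 1..9 each form their own bin and
#' everything at 10 or more is pooled into the `"10+"` bin, giving the
#' 10 distinct separation classes used throughout.
#'
#' @param d Integer vector of sequence separations (>= 1).
#' @param d_max_single Largest separation kept as its own bin.
#' @return Character vector of bin labels (`"1"`, ..., `"9"`, `"10+"`).
#' @export
d_bin_label <- function(d, d_max_single = 9L) {
  ifelse(d > d_max_single, paste0(d_max_single + 1L, "+"), as.character(d))
}

#' All separation-bin labels in order
#' @param d_max_single Largest separation kept as its own bin.
#' @return Character vector of the bin labels.
#' @export
d_bin_labels <- function(d_max_single = 9L) {
  c(as.character(seq_len(d_max_single)), paste0(d_max_single + 1L, "+"))
}

# candidate intra-chain residue pairs whose atoms can be in contact.
# method "grid": cell list with cell size = max atom-atom cutoff, so any
# contacting atom pair falls in the same or adjacent cells; "naive":
# all intra-chain pairs.
.candidate_pairs <- function(at, probe_radius, method = "grid") {
  ruid <- match(paste(at$chain, at$res_index), unique(paste(at$chain, at$res_index)))
  nres <- max(ruid)
  chain_of <- at$chain[!duplicated(ruid)]
  index_of <- at$res_index[!duplicated(ruid)]
  if (method == "naive") {
    pr <- which(upper.tri(matrix(0, nres, nres)), arr.ind = TRUE)
    cand <- cbind(pr[, 1], pr[, 2])
  } else {
    cutoff <- 2 * max(at$radius) + 2 * probe_radius
    cell <- cbind(floor(at$x / cutoff), floor(at$y / cutoff),
                  floor(at$z / cutoff))
    key <- paste(cell[, 1], cell[, 2], cell[, 3])
    cells <- split(seq_len(nrow(at)), key)
    coords <- unique(cell)
    ckey <- paste(coords[, 1], coords[, 2], coords[, 3])
    pairs <- new.env(parent = emptyenv())
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (ci in seq_along(ckey)) {
      ia <- cells[[ckey[ci]]]
      for (oi in seq_len(nrow(offs))) {
        nb <- coords[ci, ] + offs[oi, ]
        nbkey <- paste(nb[1], nb[2], nb[3])
        ib <- cells[[nbkey]]
        if (is.null(ib)) next
        for (a in ia) {
          d2 <- (at$x[ib] - at$x[a])^2 + (at$y[ib] - at$y[a])^2 +
            (at$z[ib] - at$z[a])^2
          ok <- ib[d2 <= (at$radius[a] + at$radius[ib] + 2 * probe_radius)^2]
          for (b in ok) {
            ri <- ruid[a]; rj <- ruid[b]
            if (ri < rj) assign(paste(ri, rj), TRUE, envir = pairs)
          }
        }
      }
    }
    keys <- ls(pairs)
    if (!length(keys)) {
      cand <- matrix(integer(0), ncol = 2)
    } else {
      cand <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
    }
  }
  if (nrow(cand)) {
    same_chain <- chain_of[cand[, 1]] == chain_of[cand[, 2]]
    cand <- cand[same_chain, , drop = FALSE]
  }
  list(cand = cand, ruid = ruid, chain_of = chain_of, index_of = index_of)
}

#' Per-structure contact table
#'
#' Computes the contact area of every intra-chain residue pair (i, j)
#' with j > i and nonzero area, together with its sequence separation
#' `d = res_index(j) - res_index(i)` and separation bin.  Inter-chain
#' and intra-residue contacts are excluded.  A spatial cell grid
#' prefilters candidate pairs (near-linear cost in atom count); results
#' are identical to the all-pairs computation.
#'
#' @param structure A `contactpot_structure` with radii assigned.
#' @param probe_radius Probe radius Rp, Angstrom (default 0.25).
#' @param n_points Sample points per atom sphere (default 1024).
#' @param d_max_single Largest separation kept as its own bin (default 9;
#'   larger separations pool into `"10+"`).
#' @param method `"grid"` (cell-list prefilter) or `"naive"` (all pairs).
#' @return A `contact_table`: list with `structure_id`, `probe_radius`,
#'   `n_points` and `records`, a data.frame with columns `chain`, `i`,
#'   `j`, `aa_i`, `aa_j` (sorted so `aa_i <= aa_j`), `d`, `d_bin`,
#'   `area`, ordered by (chain, i, j).
#' @export
structure_contact_table <- function(structure, probe_radius = 0.25,
                                    n_points = 1024, d_max_single = 9L,
                                    method = c("grid", "naive")) {
  method <- match.arg(method)
  at <- structure$atoms
  if (anyNA(at$radius)) stop("assign_radii() must be run first")
  points <- generate_sphere_points(n_points)
  cp <- .candidate_pairs(at, probe_radius, method)
  rows <- vector("list", nrow(cp$cand))
  if (nrow(cp$cand)) {
    atom_rows <- split(seq_len(nrow(at)), cp$ruid)
    for (k in seq_len(nrow(cp$cand))) {
      ri <- cp$cand[k, 1]; rj <- cp$cand[k, 2]
      ai <- atom_rows[[ri]]; aj <- atom_rows[[rj]]
      area <- (.directed_residue_area(at, ai, aj, probe_radius, points) +
                 .directed_residue_area(at, aj, ai, probe_radius, points)) / 2
      if (area <= 0) next
      aa <- sort(c(at$aa[ai[1]], at$aa[aj[1]]))
      rows[[k]] <- data.frame(
        chain = cp$chain_of[ri],
        i = cp$index_of[ri], j = cp$index_of[rj],
        aa_i = aa[1], aa_j = aa[2],
        d = cp$index_of[rj] - cp$index_of[ri],
        area = area, stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(0), i = integer(0), j = integer(0),
               aa_i = character(0), aa_j = character(0), d = integer(0),
               area = numeric(0), stringsAsFactors = FALSE)
  rec$d_bin <- d_bin_label(rec$d, d_max_single)
  rec <- rec[order(rec$chain, rec$i, rec$j),
             c("chain", "i", "j", "aa_i", "aa_j", "d", "d_bin", "area")]
  rownames(rec) <- NULL
  obj <- list(structure_id = structure$id, probe_radius = probe_radius,
              n_points = as.integer(n_points), records = rec)
  class(obj) <- "contact_table"
  obj
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("<contact_table> %s: %d contacting pairs (Rp = %g A, %d pts)\n",
              x$structure_id, nrow(x$records), x$probe_radius, x$n_points))
  invisible(x)
}

#' Write / read a contact table as TSV
#'
#' Deterministic row order (chain, i, j); columns `structure_id`, `aa_i`,
#' `aa_j`, `d`, `d_bin`, `probe_radius`, `area_A2` plus the residue
#' indices.
#'
#' @param table A `contact_table`.
#' @param path Output path.
#' @return `path` invisibly (write) / a `contact_table` (read).
#' @export
write_contact_table <- function(table, path) {
  rec <- table$records
  out <- data.frame(structure_id = table$structure_id,
                    chain = rec$chain, i = rec$i, j = rec$j,
                    aa_i = rec$aa_i, aa_j = rec$aa_j,
                    d = rec$d, d_bin = rec$d_bin,
                    probe_radius = table$probe_radius,
                    n_points = table$n_points,
                    area_A2 = sprintf("%.6f", rec$area))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_table
#' @export
read_contact_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(d_bin = "character"))
  rec <- data.frame(chain = as.character(tab$chain), i = tab$i, j = tab$j,
                    aa_i = tab$aa_i, aa_j = tab$aa_j, d = tab$d,
                    d_bin = as.character(tab$d_bin),
                    area = as.numeric(tab$area_A2),
                    stringsAsFactors = FALSE)
  obj <- list(structure_id = tab$structure_id[1],
              probe_radius = tab$probe_radius[1],
              n_points = as.integer(tab$n_points[1]), records = rec)
  class(obj) <- "contact_table"
  obj
}
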