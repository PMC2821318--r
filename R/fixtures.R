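# Synthetic structures, training corpora and decoy ensembles.
#
# Toy structures carry an idealized backbone (standard bond lengths and
# angles, chosen phi/psi) with side chains represented through C-beta;
# that is enough to exercise every geometric property of the contact
# engine while keeping the generator free of rotamer modelling.

# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards (generators are pure functions of the seed)
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# place atom D from A-B-C with given bond length (C-D), bond angle
# (B-C-D, degrees) and dihedral A-B-C-D (degrees)
.place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B
  bc_n <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc_n[3] - ab[3] * bc_n[2],
         ab[3] * bc_n[1] - ab[1] * bc_n[3],
         ab[1] * bc_n[2] - ab[2] * bc_n[1])
  n_n <- n / sqrt(sum(n^2))
  m <- c(n_n[2] * bc_n[3] - n_n[3] * bc_n[2],
         n_n[3] * bc_n[1] - n_n[1] * bc_n[3],
         n_n[1] * bc_n[2] - n_n[2] * bc_n[1])
  C + (-bond * cos(ang)) * bc_n +
    (bond * sin(ang) * cos(tor)) * m -
    (bond * sin(ang) * sin(tor)) * n_n
}

# ideal backbone parameters (lengths A, angles degrees)
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ca_cb = 1.521,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8, omega = 180)

# C-beta from N, CA, C: out-of-plane tetrahedral construction giving
# ~110.4 degree N-CA-CB and C-CA-CB angles
.place_cb <- function(N, CA, C) {
  b1 <- N - CA; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- C - CA; b2 <- b2 / sqrt(sum(b2^2))
  m <- -(b1 + b2); m <- m / sqrt(sum(m^2))
  nn <- c(b2[2] * b1[3] - b2[3] * b1[2],
          b2[3] * b1[1] - b2[1] * b1[3],
          b2[1] * b1[2] - b2[2] * b1[1])
  nn <- nn / sqrt(sum(nn^2))
  g <- 52 * pi / 180
  CA + .BB$ca_cb * (cos(g) * m + sin(g) * nn)
}

#' Generate an idealized toy structure
#'
#' Builds a single-chain polypeptide with ideal backbone geometry at
#' fixed backbone torsions: phi/psi = (-57, -47) for `"helix"`,
#' (-120, 120) for `"extended"`.  Atoms per residue are N, CA, C, O and
#' (except glycine) CB.  Deterministic given the seed.
#'
#' @param n_residues Number of residues (>= 2).
#' @param geometry `"helix"` or `"extended"`.
#' @param sequence One-letter amino-acid string of length `n_residues`,
#'   or `"random"` to draw uniformly from the 20 standard types.
#' @param seed RNG seed (used only when `sequence = "random"`).
#' @param id Structure identifier.
#' @return A `contactpot_structure` with radii already assigned.
#' @export
make_toy_structure <- function(n_residues, geometry = c("helix", "extended"),
                               sequence = "random", seed = 1,
                               id = NULL) {
  geometry <- match.arg(geometry)
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues < 2L) stop("need at least 2 residues")
  tor <- switch(geometry,
                helix = c(phi = -57, psi = -47),
                extended = c(phi = -120, psi = 120))
  aa <- if (identical(sequence, "random")) {
    with_seed(seed, sample(aa_alphabet(), n_residues, replace = TRUE))
  } else {
    s <- strsplit(sequence, "")[[1]]
    if (length(s) != n_residues) {
      stop("sequence length ", length(s), " != n_residues ", n_residues)
    }
    if (!all(s %in% aa_alphabet())) stop("non-standard amino-acid code")
    s
  }
  if (is.null(id)) id <- sprintf("toy_%s_%d", geometry, n_residues)

  rows <- list()
  N <- CA <- C <- NULL
  for (i in seq_len(n_residues)) {
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- c(.BB$n_ca, 0, 0)
      a <- .BB$ang_n_ca_c * pi / 180
      C <- CA + .BB$ca_c * c(-cos(a), sin(a), 0)
    } else {
      Np <- N; CAp <- CA; Cp <- C
      N <- .place_atom(Np, CAp, Cp, .BB$c_n, .BB$ang_ca_c_n, tor["psi"])
      CA <- .place_atom(CAp, Cp, N, .BB$n_ca, .BB$ang_c_n_ca, .BB$omega)
      C <- .place_atom(Cp, N, CA, .BB$ca_c, .BB$ang_n_ca_c, tor["phi"])
    }
    O <- .place_atom(N, CA, C, .BB$c_o, .BB$ang_ca_c_o, tor["psi"] + 180)
    coords <- rbind(N = N, CA = CA, C = C, O = O)
    if (aa[i] != "G") coords <- rbind(coords, CB = .place_cb(N, CA, C))
    resid3 <- names(AA1)[match(aa[i], AA1)]
    rows[[i]] <- data.frame(
      chain = "A", resno = i, res_index = i, resid = resid3, aa = aa[i],
      elety = rownames(coords),
      elesy = substr(rownames(coords), 1L, 1L),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      radius = NA_real_, stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  rownames(at) <- NULL
  assign_radii(new_structure(id, at))
}

#' Construct a decoy set
#'
#' @param native Native `contactpot_structure`.
#' @param decoys Non-empty list of decoy structures.
#' @param name Set name.
#' @return An object of class `decoy_set`.
#' @export
decoy_set <- function(native, decoys, name = native$id) {
  if (!length(decoys)) stop("decoy list is empty")
  obj <- list(native = native, decoys = decoys, name = name)
  class(obj) <- "decoy_set"
  obj
}

#' Generate a perturbed decoy ensemble from a native structure
#'
#' Each decoy is a copy of the native with independent Gaussian
#' coordinate noise per atom and axis: side-chain atoms at the full
#' `perturbation_scale` standard deviation, backbone atoms (N, CA, C, O,
#' OXT) at half scale -- contact-area scoring is most sensitive to
#' side-chain orientation, which this emulates.  Deterministic given the
#' seed.
#'
#' @param native A `contactpot_structure`.
#' @param n_decoys Number of decoys (>= 1).
#' @param perturbation_scale Noise standard deviation, Angstrom per axis.
#' @param seed RNG seed.
#' @param name Set name.
#' @return A `decoy_set`.
#' @export
make_decoy_ensemble <- function(native, n_decoys, perturbation_scale,
                                seed = 1, name = paste0(native$id, "_set")) {
  n_decoys <- as.integer(n_decoys)
  if (is.na(n_decoys) || n_decoys < 1L) stop("need at least 1 decoy")
  backbone <- native$atoms$elety %in% c("N", "CA", "C", "O", "OXT")
  sds <- ifelse(backbone, perturbation_scale / 2, perturbation_scale)
  na <- nrow(native$atoms)
  decoys <- with_seed(seed, lapply(seq_len(n_decoys), function(k) {
    dec <- native
    dec$id <- sprintf("%s_decoy%03d", native$id, k)
    dec$atoms$x <- dec$atoms$x + stats::rnorm(na, 0, sds)
    dec$atoms$y <- dec$atoms$y + stats::rnorm(na, 0, sds)
    dec$atoms$z <- dec$atoms$z + stats::rnorm(na, 0, sds)
    dec
  }))
  decoy_set(native, decoys, name)
}

#' Generate a synthetic training corpus with planted pair preferences
#'
#' Emits contact tables (not structures) whose per-pair total areas are
#' drawn as `w_a * w_b * enrichment[a, b] * noise`, i.e. a
#' marginal-product baseline modulated by a planted preference matrix
#' K* and multiplicative lognormal noise with unit mean and coefficient
#' of variation `area_noise_cv`.  Training on such a corpus should
#' recover K close to K*, which is what the potential-recovery tests
#' check.
#'
#' @param n_structures Number of synthetic structures.
#' @param pair_enrichment Symmetric positive 20x20 matrix K* (default:
#'   all 1, the uniform reference corpus).
#' @param area_noise_cv Coefficient of variation of the lognormal area
#'   noise (0 for a deterministic corpus).
#' @param seed RNG seed.
#' @param type_weights Length-20 positive marginal weights w (default
#'   all 1).
#' @param d_bins Separation bin(s) the planted contacts are filed under
#'   (default `"1"`); each listed bin receives an independent draw of
#'   the same planted model.
#' @param base_area Overall area scale in square Angstrom.
#' @return List of `contact_table` objects.
#' @export
make_planted_corpus <- function(n_structures, pair_enrichment = NULL,
                                area_noise_cv = 0, seed = 1,
                                type_weights = NULL, d_bins = "1",
                                base_area = 10) {
  aa <- aa_alphabet()
  if (is.null(pair_enrichment)) {
    pair_enrichment <- matrix(1, 20, 20, dimnames = list(aa, aa))
  }
  if (!isTRUE(all.equal(pair_enrichment, t(pair_enrichment))) ||
      any(pair_enrichment <= 0)) {
    stop("pair_enrichment must be symmetric and positive")
  }
  if (is.null(type_weights)) type_weights <- stats::setNames(rep(1, 20), aa)
  idx <- which(upper.tri(matrix(0, 20, 20), diag = TRUE), arr.ind = TRUE)
  mean_area <- base_area * type_weights[idx[, 1]] * type_weights[idx[, 2]] *
    pair_enrichment[idx]
  sdlog <- sqrt(log(1 + area_noise_cv^2))
  with_seed(seed, lapply(seq_len(n_structures), function(s) {
    rec <- do.call(rbind, lapply(d_bins, function(b) {
      noise <- if (area_noise_cv > 0) {
        stats::rlnorm(nrow(idx), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, nrow(idx))
      data.frame(
        chain = "A", i = 0L, j = 0L,
        aa_i = aa[idx[, 1]], aa_j = aa[idx[, 2]],
        d = as.integer(sub("\\+", "", b)), d_bin = b,
        area = unname(mean_area * noise), stringsAsFactors = FALSE)
    }))
    obj <- list(structure_id = sprintf("planted_%04d", s),
                probe_radius = 0.25, n_points = 1024L, records = rec)
    class(obj) <- "contact_table"
    obj
  }))
}

#' Read a decoy-set manifest
#'
#' The manifest is a TSV with columns `set_name`, `native_path`,
#' `decoy_glob`; paths are resolved relative to the manifest's
#' directory.  Each row becomes a `decoy_set` of parsed structures with
#' radii assigned.  Sets whose native file is missing are skipped with a
#' warning.
#'
#' @param path Manifest path.
#' @return List of `decoy_set` objects.
#' @export
read_decoy_manifest <- function(path) {
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("set_name", "native_path", "decoy_glob") %in% names(man)))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  out <- list()
  for (k in seq_len(nrow(man))) {
    nat_path <- resolve(man$native_path[k])
    if (!file.exists(nat_path)) {
      warning("skipping set '", man$set_name[k], "': missing native ",
              nat_path, call. = FALSE)
      next
    }
    native <- assign_radii(parse_pdb(nat_path))
    decoy_files <- Sys.glob(resolve(man$decoy_glob[k]))
    decoy_files <- setdiff(decoy_files, nat_path)
    decoys <- lapply(decoy_files, function(f) assign_radii(parse_pdb(f)))
    out[[length(out) + 1L]] <- decoy_set(native, decoys, man$set_name[k])
  }
  out
}
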