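# Decoy-set discrimination statistics: native rank, Z-score, Pe and
# coordinate RMSD after optimal (Kabsch) superposition.

#' Coordinate RMSD after optimal rigid-body superposition
#'
#' Superimposes `coords_b` onto `coords_a` with the Kabsch algorithm
#' (centroid translation plus the SVD rotation, determinant-corrected to
#' a proper rotation) and returns the root-mean-square deviation of the
#' paired points.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices (n >= 3), Angstrom.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (!all(dim(A) == dim(B))) stop("coordinate sets differ in size")
  if (nrow(A) < 3L) stop("need at least 3 points")
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  s <- svd(crossprod(B, A))                     # 3x3 covariance B^T A
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)      # proper rotation
  diffs <- B %*% R - A
  sqrt(sum(diffs^2) / nrow(A))
}

# C-alpha coordinates of a structure, in residue order
ca_coords <- function(structure) {
  at <- structure$atoms[structure$atoms$elety == "CA", , drop = FALSE]
  as.matrix(at[order(at$chain, at$res_index), c("x", "y", "z")])
}

#' Rank of the native energy among decoys
#'
#' Rank 1 is best.  Ties do not worsen the native's rank: the rank is
#' one plus the number of decoys with strictly lower energy.
#'
#' @param e_native Native-structure energy.
#' @param decoy_energies Numeric vector of decoy energies (non-empty).
#' @return Integer rank in 1..(1 + number of decoys).
#' @export
rank_native <- function(e_native, decoy_energies) {
  if (!length(decoy_energies)) stop("no decoy energies")
  1L + sum(decoy_energies < e_native)
}

#' Z-score of the native energy against the decoy distribution
#'
#' `Z = (E_native - mean(E_decoy)) / sd(E_decoy)` with the population
#' (divide-by-N) standard deviation.  More negative is better.
#'
#' @inheritParams rank_native
#' @return The Z-score.
#' @export
z_score <- function(e_native, decoy_energies) {
  if (length(decoy_energies) < 2L) stop("need at least 2 decoy energies")
  mu <- mean(decoy_energies)
  sigma <- sqrt(mean((decoy_energies - mu)^2))
  if (sigma == 0) stop("decoy energies have zero spread; Z undefined")
  (e_native - mu) / sigma
}

#' Pe rank-based discrimination score
#'
#' `Pe = ln(rank_native / n_structures)`: the natural-log fraction of
#' the structure pool ranked at or above the native.  Zero (native ranked
#' last) is the worst possible value; large negative values indicate a
#' native ranked first in a large pool.
#'
#' @param rank_native Rank of the native structure (1 = best).
#' @param n_structures Total number of structures in the set (native
#'   plus decoys).
#' @return The Pe value (<= 0).
#' @export
pe_score <- function(rank_native, n_structures) {
  if (rank_native < 1 || n_structures < 1) stop("rank and size must be >= 1")
  if (rank_native > n_structures) {
    stop("rank_native (", rank_native, ") exceeds n_structures (",
         n_structures, ")")
  }
  log(rank_native / n_structures)
}

#' Evaluate a decoy set with a trained potential
#'
#' Scores the native and every decoy with [score_structure()], then
#' assembles the discrimination statistics: native rank, Z-score, Pe,
#' and per-decoy (C-alpha RMSD to native, energy) pairs.  Decoys that
#' fail scoring are skipped and counted; decoys whose C-alpha count
#' differs from the native are excluded from RMSD (NA) but kept in the
#' ranking.
#'
#' @param decoy_set A `decoy_set` (see [make_decoy_ensemble()] or
#'   [read_decoy_manifest()]).
#' @param potential A `contact_potential`.
#' @param d_filter Separation bins to score (default `"1"`).
#' @return Object of class `decoy_evaluation`: list with `set_name`,
#'   `e_native`, `decoy_energies`, `rank_native`, `z_score`, `pe`,
#'   `n_structures`, `n_skipped` and `decoys` (data.frame decoy_id,
#'   energy, rmsd).
#' @export
evaluate_decoy_set <- function(decoy_set, potential, d_filter = "1") {
  stopifnot(inherits(decoy_set, "decoy_set"))
  e_native <- score_structure(decoy_set$native, potential,
                              d_filter = d_filter)$total_energy
  ca_nat <- ca_coords(decoy_set$native)
  ids <- character(0); energies <- numeric(0); rmsds <- numeric(0)
  n_skipped <- 0L
  for (dec in decoy_set$decoys) {
    e <- tryCatch(score_structure(dec, potential,
                                  d_filter = d_filter)$total_energy,
                  error = function(err) {
                    warning("skipping unscorable decoy '", dec$id, "': ",
                            conditionMessage(err), call. = FALSE)
                    NULL
                  })
    if (is.null(e)) { n_skipped <- n_skipped + 1L; next }
    ca_dec <- ca_coords(dec)
    r <- if (nrow(ca_dec) == nrow(ca_nat)) {
      kabsch_rmsd(ca_nat, ca_dec)
    } else NA_real_
    ids <- c(ids, dec$id); energies <- c(energies, e); rmsds <- c(rmsds, r)
  }
  if (!length(energies)) stop("no scorable decoys in set ", decoy_set$name)
  rk <- rank_native(e_native, energies)
  z <- tryCatch(z_score(e_native, energies), error = function(e) NA_real_)
  obj <- list(set_name = decoy_set$name,
              e_native = e_native,
              decoy_energies = energies,
              rank_native = rk,
              z_score = z,
              pe = pe_score(rk, 1L + length(energies)),
              n_structures = 1L + length(energies),
              n_skipped = n_skipped,
              decoys = data.frame(decoy_id = ids, energy = energies,
                                  rmsd = rmsds, stringsAsFactors = FALSE))
  class(obj) <- "decoy_evaluation"
  obj
}

#' @export
print.decoy_evaluation <- function(x, ...) {
  cat(sprintf(paste0("<decoy_evaluation> %s: rank %d/%d, Z = %s, ",
                     "Pe = %.2f\n"),
              x$set_name, x$rank_native, x$n_structures,
              ifelse(is.na(x$z_score), "n/a", sprintf("%.2f", x$z_score)),
              x$pe))
  invisible(x)
}

#' Summarise decoy evaluations as a report table
#'
#' One row per evaluated set with the discrimination columns
#' (set, n_decoys, rank_native, z_score, pe, n_skipped).
#'
#' @param evaluations List of `decoy_evaluation` objects.
#' @return A data.frame.
#' @export
evaluation_report <- function(evaluations) {
  do.call(rbind, lapply(evaluations, function(ev) {
    data.frame(set = ev$set_name,
               n_decoys = ev$n_structures - 1L,
               rank_native = ev$rank_native,
               z_score = ev$z_score,
               pe = ev$pe,
               n_skipped = ev$n_skipped,
               stringsAsFactors = FALSE)
  }))
}

#' Scatter plot of energy against RMSD for a decoy evaluation
#'
#' @param evaluation A `decoy_evaluation`.
#' @param path PNG output path.
#' @return `path` invisibly.
#' @export
plot_energy_vs_rmsd <- function(evaluation, path) {
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  d <- evaluation$decoys
  graphics::plot(d$rmsd, d$energy, pch = 19, col = "grey40",
                 xlab = "C-alpha RMSD to native (A)",
                 ylab = "contact-area energy",
                 main = evaluation$set_name,
                 xlim = range(c(0, d$rmsd), na.rm = TRUE),
                 ylim = range(c(evaluation$e_native, d$energy)))
  graphics::points(0, evaluation$e_native, pch = 17, col = "red", cex = 1.4)
  graphics::legend("bottomright", pch = c(17, 19),
                   col = c("red", "grey40"),
                   legend = c("native", "decoys"), bty = "n")
  invisible(path)
}
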