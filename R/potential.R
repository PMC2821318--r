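# Training the contact-area preference coefficients K and the mean-force
# potential E, and scoring structures with them.
#
# For each separation bin d, let A_ab be the mean (over training
# structures) of a structure's total contact area between residue types
# a and b, held in a symmetric 20x20 matrix (a pair (a,b), a != b,
# contributes its area to both the [a,b] and [b,a] cells; like-type
# pairs to the diagonal once).  With A_a = sum_b A_ab (type marginal)
# and A = sum_ab A_ab (grand total), the preference coefficient is the
# observed/expected area ratio
#
#     K(a,b,d) = A_ab * A / (A_a * A_b)
#
# which equals 1 when pair areas follow the marginal product (the
# reference state), and the potential is the Boltzmann inversion
#
#     E(a,b,d) = -T * ln K~(a,b,d),   K~ = (K * n_obs + 1) / (n_obs + 1)
#
# with n_obs the number of training structures showing the pair, so that
# unobserved pairs get E = 0 rather than an infinite penalty.

.empty_aa_matrix <- function() {
  aa <- aa_alphabet()
  matrix(0, 20L, 20L, dimnames = list(aa, aa))
}

# symmetric per-structure total-area matrix for one d bin
.structure_area_matrix <- function(records, bin) {
  M <- .empty_aa_matrix()
  r <- records[records$d_bin == bin, , drop = FALSE]
  if (nrow(r)) {
    for (k in seq_len(nrow(r))) {
      a <- r$aa_i[k]; b <- r$aa_j[k]
      M[a, b] <- M[a, b] + r$area[k]
      if (a != b) M[b, a] <- M[b, a] + r$area[k]
    }
  }
  M
}

#' Training-set contact-area averages
#'
#' Accumulates, per separation bin, the mean per-structure total contact
#' area for every residue-type pair (each training structure contributes
#' its total once, so large proteins do not dominate), the per-type
#' marginals and the grand total.
#'
#' @param tables List of `contact_table` objects computed with one and
#'   the same probe radius and point count.
#' @param d_max_single Largest separation kept as its own bin.
#' @return Object of class `training_averages`: list with `A_ab` (list of
#'   symmetric 20x20 matrices, one per bin), `A_a` (list of length-20
#'   marginals), `A_all` (named numeric, one per bin), `n_obs` (list of
#'   20x20 observation-support counts), `n_structures`, `probe_radius`,
#'   `n_points`.
#' @export
accumulate_averages <- function(tables, d_max_single = 9L) {
  if (!length(tables)) stop("empty training corpus")
  pr <- unique(vapply(tables, `[[`, numeric(1), "probe_radius"))
  np <- unique(vapply(tables, `[[`, integer(1), "n_points"))
  if (length(pr) > 1L || length(np) > 1L) {
    stop("all contact tables must share probe_radius and n_points")
  }
  bins <- d_bin_labels(d_max_single)
  S <- lapply(bins, function(b) .empty_aa_matrix())
  counts <- lapply(bins, function(b) .empty_aa_matrix())
  names(S) <- names(counts) <- bins
  for (tb in tables) {
    for (b in bins) {
      M <- .structure_area_matrix(tb$records, b)
      S[[b]] <- S[[b]] + M
      counts[[b]] <- counts[[b]] + (M > 0)
    }
  }
  n <- length(tables)
  counts <- lapply(counts, function(M) { mode(M) <- "integer"; M })
  A_ab <- lapply(S, function(M) M / n)
  obj <- list(A_ab = A_ab,
              A_a = lapply(A_ab, rowSums),
              A_all = vapply(A_ab, sum, numeric(1)),
              n_obs = counts,
              n_structures = n,
              probe_radius = pr, n_points = np,
              d_bins = bins)
  class(obj) <- "training_averages"
  obj
}

#' Preference coefficients K from training averages
#'
#' `K(a,b,d) = A_ab(d) * A_all(d) / (A_a(d) * A_b(d))`: the ratio of the
#' observed mean pair area to the area expected from the type marginals
#' alone.  K = 1 is the reference state (no preference).  Pairs whose
#' marginal product is zero (a type never observed in that bin) get K = 0
#' and are handled by the pseudocount smoothing in [compute_E()].
#'
#' @param avgs A `training_averages` object.
#' @return List of symmetric 20x20 K matrices, one per separation bin.
#' @export
compute_K <- function(avgs) {
  lapply(avgs$d_bins, function(b) {
    M <- avgs$A_ab[[b]]
    marg <- avgs$A_a[[b]]
    denom <- outer(marg, marg)
    K <- .empty_aa_matrix()
    ok <- denom > 0
    K[ok] <- M[ok] * avgs$A_all[[b]] / denom[ok]
    K
  }) |> stats::setNames(avgs$d_bins)
}

#' Mean-force potential E from preference coefficients
#'
#' Boltzmann inversion `E = -temperature_factor * ln(K~)` of the
#' pseudocount-smoothed coefficient
#' `K~ = (K * n_obs + 1) / (n_obs + 1)`, which pulls poorly supported
#' pairs toward the K = 1 reference (E = 0) and keeps E finite
#' everywhere.
#'
#' @param K List of per-bin K matrices from [compute_K()].
#' @param n_obs List of per-bin observation-support count matrices.
#' @param temperature_factor Energy scale T (default 1, RT-like units).
#' @return List of symmetric 20x20 E matrices, one per bin.
#' @export
compute_E <- function(K, n_obs, temperature_factor = 1) {
  out <- lapply(names(K), function(b) {
    Ksm <- (K[[b]] * n_obs[[b]] + 1) / (n_obs[[b]] + 1)
    -temperature_factor * log(Ksm)
  })
  stats::setNames(out, names(K))
}

#' Train a contact-area potential from contact tables
#'
#' Convenience wrapper: [accumulate_averages()] -> [compute_K()] ->
#' [compute_E()].
#'
#' @inheritParams accumulate_averages
#' @inheritParams compute_E
#' @return An object of class `contact_potential`: list with
#'   `probe_radius`, `n_points`, `d_bins`, `K`, `E`, `n_obs`,
#'   `n_structures`, `temperature_factor`.
#' @export
train_potential <- function(tables, d_max_single = 9L,
                            temperature_factor = 1) {
  avgs <- accumulate_averages(tables, d_max_single)
  K <- compute_K(avgs)
  E <- compute_E(K, avgs$n_obs, temperature_factor)
  obj <- list(probe_radius = avgs$probe_radius, n_points = avgs$n_points,
              d_bins = avgs$d_bins, K = K, E = E, n_obs = avgs$n_obs,
              n_structures = avgs$n_structures,
              temperature_factor = temperature_factor)
  class(obj) <- "contact_potential"
  obj
}

#' @export
print.contact_potential <- function(x, ...) {
  cat(sprintf(paste0("<contact_potential> Rp = %g A, %d pts/atom, ",
                     "%d separation bins, trained on %d structures\n"),
              x$probe_radius, x$n_points, length(x$d_bins),
              x$n_structures))
  invisible(x)
}

#' Score a contact table against a trained potential
#'
#' @param table A `contact_table` computed with the potential's probe
#'   radius.
#' @param potential A `contact_potential`.
#' @param d_filter Separation-bin labels to include (default `"1"`:
#'   consecutive neighbours only, the best-discriminating profile).
#' @param use_K Multiply areas by the raw preference K instead of the
#'   energy E (default FALSE).
#' @return Object of class `score_result`: list with `structure_id`,
#'   `total_energy` and `contributions` (data.frame i, j, d_bin, area,
#'   coef, term).
#' @export
score_contact_table <- function(table, potential, d_filter = "1",
                                use_K = FALSE) {
  if (!isTRUE(all.equal(table$probe_radius, potential$probe_radius))) {
    stop("contact table probe radius ", table$probe_radius,
         " does not match potential probe radius ", potential$probe_radius)
  }
  bad <- setdiff(d_filter, potential$d_bins)
  if (length(bad)) stop("unknown separation bin(s): ",
                        paste(bad, collapse = ", "))
  rec <- table$records[table$records$d_bin %in% d_filter, , drop = FALSE]
  mats <- if (use_K) potential$K else potential$E
  coef <- numeric(nrow(rec))
  if (nrow(rec)) {
    for (k in seq_len(nrow(rec))) {
      coef[k] <- mats[[rec$d_bin[k]]][rec$aa_i[k], rec$aa_j[k]]
    }
  }
  contrib <- data.frame(i = rec$i, j = rec$j, d_bin = rec$d_bin,
                        area = rec$area, coef = coef,
                        term = rec$area * coef, stringsAsFactors = FALSE)
  obj <- list(structure_id = table$structure_id,
              total_energy = sum(contrib$term), contributions = contrib)
  class(obj) <- "score_result"
  obj
}

#' Score a structure with a trained potential
#'
#' Computes the structure's contact table at the potential's probe radius
#' and point count, then sums `area x E` over the requested separation
#' bins (the total score is the contact area weighted by the potential
#' coefficient, summed over all pairs).
#'
#' @param structure A `contactpot_structure` with radii assigned.
#' @param potential A `contact_potential`.
#' @inheritParams score_contact_table
#' @return A `score_result`.
#' @export
score_structure <- function(structure, potential, d_filter = "1",
                            use_K = FALSE) {
  if (n_residues(structure) < 2L) {
    stop("structure has fewer than 2 residues")
  }
  tab <- structure_contact_table(structure,
                                 probe_radius = potential$probe_radius,
                                 n_points = potential$n_points,
                                 d_max_single = sum(!grepl("\\+", potential$d_bins)))
  score_contact_table(tab, potential, d_filter = d_filter, use_K = use_K)
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> %s: total energy %.4f over %d contacts\n",
              x$structure_id, x$total_energy, nrow(x$contributions)))
  invisible(x)
}

#' Save / load a trained potential (TSV)
#'
#' The file carries a `#`-prefixed header block (probe_radius, n_points,
#' d_bins, n_training_structures, temperature_factor, format version)
#' followed by one row per (d_bin, aa_i, aa_j) with `aa_i <= aa_j`,
#' columns K, E, n_obs.  Loading validates symmetry and bin completeness.
#'
#' @param potential A `contact_potential`.
#' @param path File path.
#' @return `path` invisibly (save) / a `contact_potential` (load).
#' @export
save_potential <- function(potential, path) {
  aa <- aa_alphabet()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# contactpot_potential_format: 1",
               sprintf("# probe_radius: %.17g", potential$probe_radius),
               sprintf("# n_points: %d", potential$n_points),
               sprintf("# d_bins: %s", paste(potential$d_bins, collapse = ",")),
               sprintf("# n_training_structures: %d", potential$n_structures),
               sprintf("# temperature_factor: %.17g",
                       potential$temperature_factor)), con)
  writeLines("d_bin\taa_i\taa_j\tK\tE\tn_obs", con)
  idx <- which(upper.tri(matrix(0, 20, 20), diag = TRUE), arr.ind = TRUE)
  for (b in potential$d_bins) {
    K <- potential$K[[b]]; E <- potential$E[[b]]; n <- potential$n_obs[[b]]
    writeLines(sprintf("%s\t%s\t%s\t%.17g\t%.17g\t%d",
                       b, aa[idx[, 1]], aa[idx[, 2]],
                       K[idx], E[idx], n[idx]), con)
  }
  invisible(path)
}

#' @rdname save_potential
#' @export
load_potential <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    row <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(row)) stop("potential file missing header field '", key, "'")
    trimws(sub("^[^:]*:", "", row[1]))
  }
  if (get_hdr("contactpot_potential_format") != "1") {
    stop("unsupported potential file format version")
  }
  d_bins <- strsplit(get_hdr("d_bins"), ",")[[1]]
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(d_bin = "character"))
  aa <- aa_alphabet()
  mk <- function(col) {
    out <- lapply(d_bins, function(b) {
      r <- tab[tab$d_bin == b, , drop = FALSE]
      # rows may appear in either order; conflicting mirrored values are
      # an asymmetry violation, missing pairs a completeness violation
      lo <- pmin(r$aa_i, r$aa_j); hi <- pmax(r$aa_i, r$aa_j)
      key <- paste(lo, hi)
      if (anyDuplicated(key)) {
        for (k in unique(key[duplicated(key)])) {
          vals <- r[[col]][key == k]
          if (max(vals) - min(vals) > 1e-12 * max(1, abs(max(vals)))) {
            stop("potential file: asymmetric ", col, " for pair ", k,
                 " in bin '", b, "'")
          }
        }
        r <- r[!duplicated(key), , drop = FALSE]
        lo <- lo[!duplicated(key)]; hi <- hi[!duplicated(key)]
      }
      if (nrow(r) != 210L) {
        stop("potential file: separation bin '", b,
             "' has ", nrow(r), " unique pairs, expected 210")
      }
      M <- .empty_aa_matrix()
      M[cbind(lo, hi)] <- r[[col]]
      M[cbind(hi, lo)] <- r[[col]]
      M
    })
    stats::setNames(out, d_bins)
  }
  K <- mk("K")
  obj <- list(probe_radius = as.numeric(get_hdr("probe_radius")),
              n_points = as.integer(get_hdr("n_points")),
              d_bins = d_bins, K = K, E = mk("E"),
              n_obs = lapply(mk("n_obs"), function(M) {
                mode(M) <- "integer"; M
              }),
              n_structures = as.integer(get_hdr("n_training_structures")),
              temperature_factor = as.numeric(get_hdr("temperature_factor")))
  class(obj) <- "contact_potential"
  obj
}
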