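# small hand-built contact table for arithmetic checks
mini_table <- function(id, aa_i, aa_j, d, area, probe = 0.25) {
  rec <- data.frame(chain = "A", i = seq_along(aa_i),
                    j = seq_along(aa_i) + d,
                    aa_i = pmin(aa_i, aa_j), aa_j = pmax(aa_i, aa_j),
                    d = d, d_bin = d_bin_label(d), area = area,
                    stringsAsFactors = FALSE)
  structure(list(structure_id = id, probe_radius = probe,
                 n_points = 1024L, records = rec),
            class = "contact_table")
}

test_that("averages are per-structure means of total pair areas", {
  t1 <- mini_table("s1", "A", "G", 1L, 5.0)
  avg1 <- accumulate_averages(list(t1))
  expect_equal(avg1$A_ab[["1"]]["A", "G"], 5.0)
  expect_equal(avg1$A_ab[["1"]]["G", "A"], 5.0)
  expect_equal(avg1$A_all[["1"]], 10.0)    # symmetric-matrix grand total
  t2 <- mini_table("s2", "A", "G", 1L, 4.0)
  t3 <- mini_table("s3", "A", "G", 1L, 6.0)
  avg2 <- accumulate_averages(list(t2, t3))
  expect_equal(avg2$A_ab[["1"]]["A", "G"], 5.0)
  expect_error(accumulate_averages(list()), "empty")
  expect_error(accumulate_averages(list(t1, mini_table("x", "A", "G", 1L,
                                                       1, probe = 0.5))),
               "probe_radius")
})

test_that("a uniform corpus is the reference state: K = 1, E = 0", {
  corp <- make_planted_corpus(4, area_noise_cv = 0)
  pot <- train_potential(corp)
  expect_lt(max(abs(pot$K[["1"]] - 1)), 1e-9)
  expect_lt(max(abs(pot$E[["1"]])), 1e-9)
})

test_that("K is linear in the observed pair area at fixed marginals", {
  corp <- make_planted_corpus(3, area_noise_cv = 0)
  avgs <- accumulate_averages(corp)
  K1 <- compute_K(avgs)
  avgs$A_ab[["1"]]["A", "L"] <- 2 * avgs$A_ab[["1"]]["A", "L"]
  avgs$A_ab[["1"]]["L", "A"] <- 2 * avgs$A_ab[["1"]]["L", "A"]
  K2 <- compute_K(avgs)
  expect_equal(K2[["1"]]["A", "L"], 2 * K1[["1"]]["A", "L"])
  expect_equal(K2[["1"]]["V", "Y"], K1[["1"]]["V", "Y"])
})

test_that("Boltzmann inversion maps K through the smoothed logarithm", {
  aa <- aa_alphabet()
  K <- list(`1` = matrix(1, 20, 20, dimnames = list(aa, aa)))
  n0 <- list(`1` = matrix(1000L, 20, 20, dimnames = list(aa, aa)))
  expect_equal(compute_E(K, n0)[["1"]],
               matrix(0, 20, 20, dimnames = list(aa, aa)),
               tolerance = 1e-3)
  K$`1`["A", "L"] <- K$`1`["L", "A"] <- exp(1)
  E <- compute_E(K, n0)[["1"]]
  expect_equal(E["A", "L"], -1, tolerance = 1e-2)
  expect_equal(E, t(E))
  # unobserved pairs are pulled to the reference state exactly
  nz <- list(`1` = matrix(0L, 20, 20, dimnames = list(aa, aa)))
  Kz <- list(`1` = matrix(0, 20, 20, dimnames = list(aa, aa)))
  expect_true(all(compute_E(Kz, nz)[["1"]] == 0))
})

test_that("K is invariant under a global rescaling of all areas", {
  corp <- make_planted_corpus(20, area_noise_cv = 0.3, seed = 12)
  pot1 <- train_potential(corp)
  scaled <- lapply(corp, function(tb) {
    tb$records$area <- tb$records$area * 7.3
    tb
  })
  pot2 <- train_potential(scaled)
  expect_equal(pot2$K[["1"]], pot1$K[["1"]], tolerance = 1e-12)
})

test_that("training recovers planted pair preferences", {
  aa <- aa_alphabet()
  enr <- matrix(1, 20, 20, dimnames = list(aa, aa))
  enr["A", "L"] <- enr["L", "A"] <- 2
  pot <- train_potential(make_planted_corpus(150, enr, area_noise_cv = 0.2,
                                             seed = 21))
  K <- pot$K[["1"]]
  up <- upper.tri(K, diag = TRUE)
  expect_gt(stats::cor(K[up], enr[up]), 0.9)
  expect_gt(K["A", "L"], 1.5)
})

test_that("scoring is the area-weighted sum of potential coefficients", {
  aa <- aa_alphabet()
  pot <- train_potential(make_planted_corpus(2, area_noise_cv = 0))
  pot$E[["1"]]["A", "G"] <- pot$E[["1"]]["G", "A"] <- -0.5
  single <- mini_table("one", "A", "G", 1L, 10.0)
  expect_equal(score_contact_table(single, pot)$total_energy, -5.0)
  empty <- mini_table("far", "A", "G", 5L, 3.0)   # outside d_filter = "1"
  expect_equal(score_contact_table(empty, pot)$total_energy, 0)
  expect_error(score_contact_table(
    mini_table("p", "A", "G", 1L, 1, probe = 0.5), pot), "probe")
})

test_that("a structure's score equals the table-potential dot product", {
  s <- make_toy_structure(10, "helix", seed = 31)
  tabs <- lapply(1:5, function(k) {
    structure_contact_table(make_toy_structure(10, "helix", seed = k),
                            0.25, 512)
  })
  pot <- train_potential(tabs)
  pot$n_points <- 512L
  res <- score_structure(s, pot, d_filter = d_bin_labels())
  # independent recomputation from the serialized contact table
  path <- tempfile(fileext = ".tsv")
  write_contact_table(structure_contact_table(s, 0.25, 512), path)
  tsv <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(d_bin = "character"))
  expected <- sum(vapply(seq_len(nrow(tsv)), function(k) {
    tsv$area_A2[k] * pot$E[[tsv$d_bin[k]]][tsv$aa_i[k], tsv$aa_j[k]]
  }, numeric(1)))
  expect_equal(res$total_energy, expected, tolerance = 1e-6)
  # linearity: total equals the sum over any partition of contributions
  expect_equal(res$total_energy, sum(res$contributions$term),
               tolerance = 1e-9)
})

test_that("potentials round-trip losslessly through the TSV format", {
  pot <- train_potential(make_planted_corpus(10, area_noise_cv = 0.4,
                                             seed = 3))
  path <- tempfile(fileext = ".tsv")
  save_potential(pot, path)
  back <- load_potential(path)
  for (b in pot$d_bins) {
    expect_identical(back$K[[b]], pot$K[[b]])
    expect_identical(back$E[[b]], pot$E[[b]])
    expect_identical(back$n_obs[[b]], pot$n_obs[[b]])
  }
  expect_identical(back$probe_radius, pot$probe_radius)
  expect_identical(back$n_structures, pot$n_structures)
})

test_that("malformed potential files are rejected with useful errors", {
  pot <- train_potential(make_planted_corpus(3, area_noise_cv = 0))
  path <- tempfile(fileext = ".tsv")
  save_potential(pot, path)
  lines <- readLines(path)
  # drop every row of bin 4 -> completeness error naming the bin
  drop4 <- lines[!grepl("^4\t", lines)]
  p1 <- tempfile(); writeLines(drop4, p1)
  expect_error(load_potential(p1), "'4'")
  # conflicting mirrored K values -> asymmetry error
  row <- grep("^1\tA\tL\t", lines)[1]
  parts <- strsplit(lines[row], "\t")[[1]]
  bad <- c(lines, paste(c("1", "L", "A", "99", parts[5], parts[6]),
                        collapse = "\t"))
  p2 <- tempfile(); writeLines(bad, p2)
  expect_error(load_potential(p2), "asymmetric")
  # wrong format version
  p3 <- tempfile()
  writeLines(sub("format: 1", "format: 99", lines), p3)
  expect_error(load_potential(p3), "format")
})
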