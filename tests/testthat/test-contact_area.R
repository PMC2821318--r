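test_that("sphere point weights sum to the full sphere area by construction", {
  for (n in c(100, 1024)) {
    pts <- generate_sphere_points(n)
    expect_equal(sum(rep(pts$point_weight(1), pts$n)), 4 * pi)
    expect_equal(sum(rep(pts$point_weight(2.25), pts$n)), 4 * pi * 2.25^2)
    norms <- sqrt(rowSums(pts$directions^2))
    expect_true(all(abs(norms - 1) < 1e-9))
  }
})

test_that("the lattice is quasi-uniform and deterministic", {
  pts <- generate_sphere_points(100)
  expect_lt(sqrt(sum(colMeans(pts$directions)^2)), 0.05)
  expect_identical(generate_sphere_points(100)$directions, pts$directions)
  expect_false(isTRUE(all.equal(generate_sphere_points(16)$directions[1, ],
                                generate_sphere_points(17)$directions[1, ])))
  expect_error(generate_sphere_points(15), ">= 16")
})

test_that("the contact criterion is distance <= Ra + Rb + 2 Rp", {
  expect_true(atoms_in_contact(c(0, 0, 0), c(4.05, 0, 0), 2.0, 1.55, 0.25))
  expect_false(atoms_in_contact(c(0, 0, 0), c(4.06, 0, 0), 2.0, 1.55, 0.25))
  expect_true(atoms_in_contact(c(1, 2, 3), c(1, 2, 3), 2.0, 2.0, 0.25))
})

test_that("directed atom area matches the analytic spherical cap", {
  pts <- generate_sphere_points(10000)
  a <- atom_pair_contact_area(c(0, 0, 0), 2.0, matrix(c(3, 0, 0), 1),
                              2.0, 0.25, pts)
  exact <- cap_area_analytic(2.0, 2.0, 0.25, 3.0)
  expect_equal(exact, 2 * pi * 2.25^2 * (1 - 2 / 3))   # 10.60 A^2
  expect_lt(abs(a - exact) / exact, 0.01)
})

test_that("degenerate partner configurations behave as expected", {
  pts <- generate_sphere_points(1024)
  far <- atom_pair_contact_area(c(0, 0, 0), 2.0, matrix(c(9, 0, 0), 1),
                                2.0, 0.25, pts)
  expect_equal(far, 0)
  # concentric engulfing partner: every point is in contact
  full <- atom_pair_contact_area(c(0, 0, 0), 1.5, matrix(c(0, 0, 0), 1),
                                 2.0, 0.25, pts)
  expect_equal(full, 4 * pi * 1.75^2)
})

test_that("each point is credited once, to the nearest contacting partner", {
  pts <- generate_sphere_points(4096)
  # two overlapping partners; total area must not double-count
  partners <- rbind(c(2.8, 0, 0), c(3.2, 0, 0))
  a <- atom_pair_contact_area(c(0, 0, 0), 2.0, partners, c(2.0, 2.0),
                              0.25, pts)
  expect_length(a, 2)
  expect_true(all(a >= 0))
  expect_lte(sum(a), 4 * pi * 2.25^2)
  # the union area equals what a single-partner union count gives:
  # every point within either partner's expanded sphere counted once
  R1 <- 2.25
  P <- pts$directions * R1
  inside <- function(centre) {
    rowSums(sweep(P, 2, centre)^2) <= (2.0 + 0.25)^2
  }
  union_count <- sum(inside(partners[1, ]) | inside(partners[2, ]))
  expect_equal(sum(a), union_count * pts$point_weight(R1))
})

test_that("contact area is non-increasing in centre distance", {
  pts <- generate_sphere_points(2048)
  dists <- seq(0.5, 4.6, by = 0.1)
  areas <- vapply(dists, function(D) {
    atom_pair_contact_area(c(0, 0, 0), 2.0, matrix(c(D, 0, 0), 1),
                           2.0, 0.25, pts)
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("residue pair area is symmetric bit-exactly", {
  s <- make_toy_structure(6, "helix", seed = 2)
  a_ij <- residue_pair_contact_area(s, 2, 3, 0.25)
  a_ji <- residue_pair_contact_area(s, 3, 2, 0.25)
  expect_identical(a_ij, a_ji)
  expect_gt(a_ij, 0)
})

test_that("areas are exactly invariant under translation", {
  s <- make_toy_structure(6, "helix", seed = 2)
  t1 <- structure_contact_table(s, 0.25, 512)
  s2 <- s
  s2$atoms$x <- s2$atoms$x + 11.25
  s2$atoms$y <- s2$atoms$y - 4
  s2$atoms$z <- s2$atoms$z + 0.33
  t2 <- structure_contact_table(s2, 0.25, 512)
  expect_lt(max(abs(t2$records$area - t1$records$area)), 1e-9)
})

test_that("rotation changes areas only at the quadrature resolution", {
  # the sample lattice is fixed in the global frame, so rotating the
  # molecule re-samples each sphere: contact pairs must be preserved
  # and areas agree to the finite-n sampling precision
  s <- make_toy_structure(6, "helix", seed = 2)
  t1 <- structure_contact_table(s, 0.25, 512)
  s2 <- s
  xyz <- random_rigid_transform(s$atoms[, c("x", "y", "z")], seed = 9)
  s2$atoms$x <- xyz[, 1]; s2$atoms$y <- xyz[, 2]; s2$atoms$z <- xyz[, 3]
  t2 <- structure_contact_table(s2, 0.25, 512)
  expect_equal(t2$records[, c("chain", "i", "j", "d")],
               t1$records[, c("chain", "i", "j", "d")])
  expect_lt(abs(sum(t2$records$area) - sum(t1$records$area)) /
              sum(t1$records$area), 0.01)
  expect_lt(max(abs(t2$records$area - t1$records$area) /
                  pmax(t1$records$area, 1)), 0.1)
})

test_that("a 3-residue chain yields separations 1 and 2 only", {
  s <- make_toy_structure(3, "extended", sequence = "AAA")
  tab <- structure_contact_table(s, 0.25, 256)
  expect_true(all(tab$records$d %in% c(1, 2)))
  expect_true(all(tab$records$area >= 0))
  expect_true(all(c(tab$records$aa_i, tab$records$aa_j) %in% aa_alphabet()))
})

test_that("grid-accelerated tables equal the all-pairs brute force exactly", {
  for (geom in c("helix", "extended")) {
    s <- make_toy_structure(10, geom, seed = 4)
    grid <- structure_contact_table(s, 0.25, 512, method = "grid")
    naive <- structure_contact_table(s, 0.25, 512, method = "naive")
    expect_identical(grid$records, naive$records)
  }
})

test_that("the engine agrees with a naive point-loop reimplementation", {
  s <- make_toy_structure(2, "extended", sequence = "GG", id = "gg")
  mine <- residue_pair_contact_area(s, 1, 2, 0.25,
                                    generate_sphere_points(2000))
  ref <- naive_residue_area(s, 1, 2, 0.25, 2000)
  expect_lt(abs(mine - ref) / ref, 0.001)
})

test_that("contact tables round-trip through TSV", {
  s <- make_toy_structure(5, "helix", seed = 6)
  tab <- structure_contact_table(s, 0.25, 256)
  path <- tempfile(fileext = ".tsv")
  write_contact_table(tab, path)
  back <- read_contact_table(path)
  expect_equal(back$structure_id, tab$structure_id)
  expect_equal(back$probe_radius, tab$probe_radius)
  expect_equal(back$records$area, tab$records$area, tolerance = 1e-6)
  expect_equal(back$records$d_bin, tab$records$d_bin)
})

test_that("positive area implies at least one atom pair within cutoff", {
  s <- make_toy_structure(8, "helix", seed = 7)
  tab <- structure_contact_table(s, 0.25, 256)
  at <- s$atoms
  for (k in seq_len(nrow(tab$records))) {
    ai <- at[at$res_index == tab$records$i[k], ]
    aj <- at[at$res_index == tab$records$j[k], ]
    any_contact <- FALSE
    for (a in seq_len(nrow(ai))) {
      for (b in seq_len(nrow(aj))) {
        if (atoms_in_contact(c(ai$x[a], ai$y[a], ai$z[a]),
                             c(aj$x[b], aj$y[b], aj$z[b]),
                             ai$radius[a], aj$radius[b], 0.25)) {
          any_contact <- TRUE
        }
      }
    }
    expect_true(any_contact)
  }
})
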