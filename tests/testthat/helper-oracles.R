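# Independent oracles used to cross-check the package implementations.
# These are deliberately naive: closed forms and brute-force loops that
# share no code with the functions they validate.

# Closed-form directed contact area of atom A (radius Ra) onto atom B
# (radius Rb) at centre distance D for probe radius Rp: the spherical
# cap of A's probe-expanded sphere (radius R1 = Ra+Rp) lying inside B's
# probe-expanded sphere (radius R2 = Rb+Rp).
cap_area_analytic <- function(Ra, Rb, Rp, D) {
  R1 <- Ra + Rp
  R2 <- Rb + Rp
  if (D >= R1 + R2) return(0)
  if (D + R1 <= R2) return(4 * pi * R1^2)   # A's sphere fully inside B's
  cost <- (D^2 + R1^2 - R2^2) / (2 * D * R1)
  cost <- max(-1, min(1, cost))
  2 * pi * R1^2 * (1 - cost)
}

# Brute-force directed residue contact area: plain loops over sample
# points and partner atoms, nearest-contacting-partner assignment.
naive_directed_area <- function(atoms_i, atoms_j, probe_radius, dirs) {
  n <- nrow(dirs)
  total <- 0
  for (a in seq_len(nrow(atoms_i))) {
    R1 <- atoms_i$radius[a] + probe_radius
    w <- R1^2 * 4 * pi / n
    ca <- c(atoms_i$x[a], atoms_i$y[a], atoms_i$z[a])
    for (p in seq_len(n)) {
      pt <- ca + R1 * dirs[p, ]
      best <- Inf
      for (b in seq_len(nrow(atoms_j))) {
        cb <- c(atoms_j$x[b], atoms_j$y[b], atoms_j$z[b])
        d2 <- sum((pt - cb)^2)
        if (d2 <= (atoms_j$radius[b] + probe_radius)^2 && d2 < best) {
          best <- d2
        }
      }
      if (is.finite(best)) total <- total + w
    }
  }
  total
}

# Symmetrized naive residue-pair area on a structure.
naive_residue_area <- function(structure, i, j, probe_radius, n_points) {
  at <- structure$atoms
  dirs <- generate_sphere_points(n_points)$directions
  ai <- at[at$res_index == i, , drop = FALSE]
  aj <- at[at$res_index == j, , drop = FALSE]
  (naive_directed_area(ai, aj, probe_radius, dirs) +
     naive_directed_area(aj, ai, probe_radius, dirs)) / 2
}

# Rotation matrix from z-y-z Euler angles.
euler_rot <- function(a, b, g) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

# Brute-force minimum RMSD over rigid motions: coarse grid over Euler
# angles followed by Nelder-Mead refinement.  Centres both sets first
# (the optimal translation always aligns centroids).
rmsd_bruteforce <- function(A, B) {
  A <- sweep(as.matrix(A), 2, colMeans(A))
  B <- sweep(as.matrix(B), 2, colMeans(B))
  f <- function(p) {
    R <- euler_rot(p[1], p[2], p[3])
    sqrt(sum((B %*% t(R) - A)^2) / nrow(A))
  }
  step <- pi / 12
  best <- c(0, 0, 0); bestv <- f(best)
  for (a in seq(0, 2 * pi - step, by = step))
    for (b in seq(0, pi, by = step))
      for (g in seq(0, 2 * pi - step, by = step)) {
        v <- f(c(a, b, g))
        if (v < bestv) { bestv <- v; best <- c(a, b, g) }
      }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# random rigid motion applied to an n x 3 coordinate matrix
random_rigid_transform <- function(X, seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  sweep(as.matrix(X) %*% t(R), 2, rnorm(3, sd = 5), "+")
}
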