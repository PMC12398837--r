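# Independent naive implementation of the descriptor pipeline (explicit
# per-pair loops, explicit 3x3 solves) used as the numerical oracle, plus
# small generators for random point-cloud molecules.

oracle_whales_indices <- function(coords, charges, reg = 1e-7) {
  n <- nrow(coords)
  w <- abs(charges)
  acm <- matrix(0, n, n)
  for (j in seq_len(n)) {
    S <- matrix(0, 3, 3)
    for (i in seq_len(n)) {
      d <- coords[i, ] - coords[j, ]
      S <- S + w[i] * (d %o% d)
    }
    S <- S / sum(w)
    eps <- reg * max(S[1, 1] + S[2, 2] + S[3, 3], 1)
    Sinv <- solve(S + diag(eps, 3))
    for (i in seq_len(n)) {
      d <- coords[i, ] - coords[j, ]
      # quadratic form d^T Sinv d as an explicit scalar double loop
      q <- 0
      for (b in 1:3) {
        u <- 0
        for (a in 1:3) u <- u + d[a] * Sinv[a, b]
        q <- q + u * d[b]
      }
      acm[i, j] <- sqrt(max(q, 0))
    }
    acm[j, j] <- 0
  }
  isolation <- numeric(n); remoteness <- numeric(n)
  for (j in seq_len(n)) {
    col <- acm[-j, j]
    isolation[j] <- min(col)
    remoteness[j] <- mean(col)
  }
  list(acm = acm, isolation = isolation, remoteness = remoteness,
       ir = isolation / remoteness)
}

# Random point-cloud "molecule": coordinates in a 6 A box, charges in
# [-0.5, 0.5] with at least one nonzero.
make_cloud <- function(n, seed, id = sprintf("cloud%d_%d", n, seed)) {
  set.seed(seed)
  coords <- matrix(stats::runif(3 * n, -3, 3), ncol = 3)
  charges <- stats::runif(n, -0.5, 0.5)
  charges[1] <- 0.4
  molecule3d(id, rep("C", n), coords, charges)
}

# Uniform random proper rotation matrix.
random_rotation <- function(seed) {
  set.seed(seed)
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigid_transform <- function(mol, rotation, translation) {
  molecule3d(mol$id, mol$elements,
             mol$coords %*% t(rotation) +
               matrix(translation, mol$n_atoms, 3, byrow = TRUE),
             mol$charges, smiles = mol$smiles, bonds = mol$bonds)
}

# The 4-atom toy used in hand-check tests: tetrahedral geometry with mixed
# charges.
toy_tetrahedron <- function() {
  coords <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  molecule3d("toy4", c("C", "H", "H", "H"), coords,
             c(0.4, -0.2, -0.1, -0.1))
}
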