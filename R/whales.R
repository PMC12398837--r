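#' Atom-centered weighted covariance matrix
#'
#' For center atom `j`, computes the 3x3 covariance of all atomic positions
#' relative to atom `j`, weighted by the absolute partial charges:
#' \deqn{S_w(j) = \frac{\sum_i |\delta_i| (x_i - x_j)(x_i - x_j)^T}
#'                    {\sum_i |\delta_i|}}
#' The self term (i = j) contributes zero. The weights are normalized, so
#' scaling every charge by the same positive constant leaves the matrix
#' unchanged.
#'
#' @param mol A [molecule3d].
#' @param j Atom index (1-based).
#' @return A symmetric positive-semidefinite 3x3 matrix (Angstrom^2).
#' @export
weighted_covariance <- function(mol, j) {
  n <- mol$n_atoms
  if (j < 1 || j > n) {
    stop_ws("atom index %d out of range 1..%d", j, n,
            class = "whalescreen_contract_error")
  }
  w <- abs(mol$charges)
  if (all(w == 0)) {
    stop_ws("molecule '%s': all partial charges are zero; the weighted covariance is undefined",
            mol$id, class = "whalescreen_degenerate_weights")
  }
  # accumulate the rank-1 terms in atom order: keeps the result numerically
  # reproducible against reference loop implementations even when S_w is
  # poorly conditioned
  S <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    d <- mol$coords[i, ] - mol$coords[j, ]
    S <- S + w[i] * (d %o% d)
  }
  S / sum(w)
}

# Ridge used before inverting S_w(j): scaled to the matrix trace so that
# planar/linear/2-atom geometries stay invertible while well-conditioned
# cases are perturbed negligibly; continuous in the input. Plain
# double-precision addition, so reference implementations of the trace
# reproduce it bitwise.
acm_ridge <- function(S, regularization) {
  regularization * max(S[1, 1] + S[2, 2] + S[3, 3], 1)
}

#' Atom-centered Mahalanobis distance matrix
#'
#' Entry (i, j) is the Mahalanobis distance of atom i from atom j measured
#' in the metric of atom j's weighted covariance matrix:
#' \deqn{ACM(i,j) = \sqrt{(x_i - x_j)^T S_w(j)^{-1} (x_i - x_j)}}
#' Each `S_w(j)` is ridge-regularized (`S + eps I` with
#' `eps = regularization * max(trace(S), 1)`) before inversion, so planar
#' and linear geometries are handled continuously. The matrix is generally
#' NOT symmetric (the metric differs per center); the diagonal is exactly
#' zero.
#'
#' @param mol A [molecule3d] with at least 2 atoms.
#' @param regularization Relative ridge (default `1e-7`).
#' @return An `n x n` matrix of nonnegative unitless distances, class
#'   `acm_matrix`.
#' @export
acm_matrix <- function(mol, regularization = 1e-7) {
  n <- mol$n_atoms
  if (n < 2) {
    stop_ws("molecule '%s': at least 2 atoms required for the ACM matrix",
            mol$id, class = "whalescreen_contract_error")
  }
  acm <- matrix(0, n, n)
  for (j in seq_len(n)) {
    S <- weighted_covariance(mol, j)
    Sr <- S + diag(acm_ridge(S, regularization), 3)
    Sinv <- solve(Sr)
    d <- sweep(mol$coords, 2, mol$coords[j, ])
    # quadratic form d^T Sinv d, written out elementwise so the arithmetic
    # follows plain scalar evaluation order (reproducible against reference
    # implementations even for ill-conditioned S_w)
    u1 <- d[, 1] * Sinv[1, 1] + d[, 2] * Sinv[2, 1] + d[, 3] * Sinv[3, 1]
    u2 <- d[, 1] * Sinv[1, 2] + d[, 2] * Sinv[2, 2] + d[, 3] * Sinv[3, 2]
    u3 <- d[, 1] * Sinv[1, 3] + d[, 2] * Sinv[2, 3] + d[, 3] * Sinv[3, 3]
    q <- u1 * d[, 1] + u2 * d[, 2] + u3 * d[, 3]
    if (any(!is.finite(q))) {
      stop_ws("molecule '%s': non-finite ACM entries for center atom %d",
              mol$id, j, class = "whalescreen_numerical_error")
    }
    acm[, j] <- sqrt(pmax(q, 0))
  }
  diag(acm) <- 0
  class(acm) <- c("acm_matrix", class(acm))
  acm
}

#' Per-atom isolation, remoteness and IR indices
#'
#' From an atom-centered Mahalanobis matrix, computes for every atom `j`:
#' * isolation `Isol(j) = min over i != j of ACM(i, j)` - distance to the
#'   nearest other atom in j's metric (local environment);
#' * remoteness `Rem(j) = mean over i != j of ACM(i, j)` - mean distance to
#'   all other atoms (global position);
#' * their ratio `IR(j) = Isol(j) / Rem(j)`.
#'
#' Both Isol and Rem are taken over the same vector of distances, the
#' column `ACM(., j)` (all other atoms measured in atom j's metric), which
#' guarantees `0 < IR(j) <= 1` since a minimum never exceeds the mean of
#' the same set.
#'
#' @param acm Matrix from [acm_matrix()].
#' @return A data frame with columns `isolation`, `remoteness`, `ir` (one
#'   row per atom), all unitless.
#' @export
atomic_indices <- function(acm) {
  n <- nrow(acm)
  if (is.null(n) || n < 2) {
    stop_ws("ACM matrix must be at least 2 x 2",
            class = "whalescreen_contract_error")
  }
  isolation <- numeric(n); remoteness <- numeric(n)
  for (j in seq_len(n)) {
    col <- acm[-j, j]
    isolation[j] <- min(col)
    remoteness[j] <- mean(col)
  }
  if (any(remoteness == 0)) {
    stop_ws("degenerate geometry: remoteness is zero for atom(s) %s (coincident atoms)",
            paste(which(remoteness == 0), collapse = ", "),
            class = "whalescreen_degenerate_geometry")
  }
  data.frame(isolation = isolation, remoteness = remoteness,
             ir = isolation / remoteness)
}

# Fixed descriptor layout: three 11-value blocks (percentiles 0,10,...,100
# of each per-atom index), concatenated as (Isol | Rem | IR).
whales_block_names <- function() {
  p <- sprintf("p%03d", seq(0, 100, 10))
  c(paste0("isol_", p), paste0("rem_", p), paste0("ir_", p))
}

#' WHALES descriptor of a prepared molecule
#'
#' Computes the 33-value WHALES vector: the percentiles 0, 10, ..., 100
#' (minimum, deciles, maximum; linear interpolation between closest ranks,
#' i.e. `stats::quantile` type 7) of each of the three per-atom indices
#' (isolation, remoteness, IR), concatenated in the fixed block order
#' (Isol | Rem | IR). Within each block values are non-decreasing by
#' construction. The descriptor is invariant under rigid motions of the
#' coordinates, under uniform scaling of the partial charges, and under
#' atom relabeling.
#'
#' @param mol A [molecule3d] with at least 3 atoms.
#' @param regularization Ridge passed to [acm_matrix()].
#' @return Named numeric vector of length 33 with attribute
#'   `molecule_id`.
#' @export
whales_descriptor <- function(mol, regularization = 1e-7) {
  if (mol$n_atoms < 3) {
    stop_ws("molecule '%s': at least 3 atoms required for a WHALES descriptor",
            mol$id, class = "whalescreen_contract_error")
  }
  idx <- tryCatch(atomic_indices(acm_matrix(mol, regularization)),
                  error = function(e) {
                    stop_ws("molecule '%s': %s", mol$id, conditionMessage(e),
                            class = class(e)[1])
                  })
  probs <- seq(0, 1, 0.1)
  v <- c(stats::quantile(idx$isolation, probs, type = 7, names = FALSE),
         stats::quantile(idx$remoteness, probs, type = 7, names = FALSE),
         stats::quantile(idx$ir, probs, type = 7, names = FALSE))
  names(v) <- whales_block_names()
  attr(v, "molecule_id") <- mol$id
  v
}

#' WHALES descriptors for a collection
#'
#' @param mols List of [molecule3d] objects (e.g. from
#'   [prepare_collection()]).
#' @param regularization Ridge passed to [acm_matrix()].
#' @return Numeric matrix, one row per molecule (rownames = molecule ids),
#'   33 named columns.
#' @export
whales_descriptors <- function(mols, regularization = 1e-7) {
  out <- t(vapply(mols, function(m) {
    as.numeric(whales_descriptor(m, regularization))
  }, numeric(33)))
  rownames(out) <- vapply(mols, `[[`, character(1), "id")
  colnames(out) <- whales_block_names()
  out
}

#' Write a descriptor matrix to CSV
#'
#' @param desc Matrix from [whales_descriptors()].
#' @param path Output CSV path (`molecule_id` + 33 named columns).
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(desc, path) {
  df <- data.frame(molecule_id = rownames(desc), desc, row.names = NULL,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor matrix written by [write_descriptors()]
#'
#' @param path CSV path.
#' @return Numeric matrix with molecule ids as rownames.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$molecule_id
  m
}
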