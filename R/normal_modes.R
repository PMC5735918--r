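#' Normal mode analysis of a Cartesian Hessian
#'
#' Standard vibrational analysis: mass-weight the Hessian, project out the
#' three translations and two (linear) or three rigid rotations, diagonalize,
#' and keep the `N_f` largest-eigenvalue vibrational modes.
#'
#' Mode normalization convention: each returned mode is unit-normalized in
#' plain Cartesian space (not mass-weighted), and its force constant is
#' defined as the quadratic form along that unit direction,
#' `K_i = q_i' H q_i` (Hartree/Angstrom^2). With this convention a geometry
#' displaced by `x * q_i` on the quadratic surface `H` has energy exactly
#' `1/2 K_i x^2`, which is the identity the thermal displacement formula
#' inverts. Quantum-chemistry codes differ in their normalization of normal
#' modes; this package fixes the convention explicitly so that sampling is
#' self-consistent whatever produced the Hessian.
#'
#' @param molecule Reference (equilibrium) geometry, an `nms_molecule`.
#' @param hessian Symmetric numeric matrix, `3*N_a x 3*N_a`, Hartree/Angstrom^2,
#'   rows/columns ordered atom-major (`x1, y1, z1, x2, ...`).
#' @param table Element table providing masses.
#' @param linear Logical; defaults to geometric detection on `molecule`.
#' @param allow_imaginary If `TRUE`, modes with non-positive curvature are
#'   dropped with a warning instead of raising an error. Optimizations that
#'   halt on a saddle point produce such modes; the thermal displacement
#'   magnitude is undefined for them, so they can never be sampled.
#' @param symmetry_tol Relative tolerance for the Hessian symmetry check.
#' @return An object of class `nms_modes`: list with `modes` (array
#'   `N_f x atoms x 3`, each slice unit Cartesian norm), `force_constants`
#'   (Hartree/Angstrom^2), `frequencies` (cm^-1, reporting only),
#'   `eigenvalues` (mass-weighted, Hartree/(amu Angstrom^2)),
#'   `projection_residual` (largest surviving rigid-body eigenvalue
#'   magnitude), `reference` (the input molecule), `hessian`, and `linear`.
#' @examples
#' toys <- toy_molecule_library()
#' nm <- normal_mode_analysis(toys$diatomic$molecule, toys$diatomic$hessian)
#' nm$force_constants  # equals the closed-form 2k for an equal-mass stretch
#' @export
normal_mode_analysis <- function(molecule, hessian, table = element_table(),
                                 linear = detect_linearity(molecule, table = table),
                                 allow_imaginary = FALSE,
                                 symmetry_tol = 1e-8) {
  na <- n_atoms(molecule)
  n3 <- 3L * na
  hessian <- as.matrix(hessian)
  if (!all(dim(hessian) == n3))
    stop("hessian must be ", n3, " x ", n3, " for ", na, " atoms")
  scale <- max(abs(hessian), 1e-300)
  if (max(abs(hessian - t(hessian))) > symmetry_tol * scale)
    stop("hessian is not symmetric within tolerance")
  hessian <- (hessian + t(hessian)) / 2

  m <- element_masses(molecule$species, table)
  w <- rep(sqrt(m), each = 3L)                 # atom-major flattening
  hmw <- hessian / tcrossprod(w)

  nf <- vibrational_dof(molecule, linear = linear)
  proj <- rigid_body_basis(molecule$coordinates, m)
  n_rigid <- ncol(proj)
  if (n3 - n_rigid != nf)
    stop("rigid-body space has rank ", n_rigid, " but linearity flag implies ",
         n3 - nf, "; check geometry or the `linear` argument")

  p <- diag(n3) - tcrossprod(proj)
  a <- p %*% hmw %*% p
  a <- (a + t(a)) / 2
  es <- eigen(a, symmetric = TRUE)             # eigenvalues decreasing

  vib_idx <- seq_len(nf)
  lambda <- es$values[vib_idx]
  residual <- max(abs(es$values[-vib_idx]))

  modes <- array(0, dim = c(nf, na, 3L))
  kvec <- numeric(nf)
  for (i in vib_idx) {
    q <- es$vectors[, i] / w                   # un-mass-weight
    q <- q / sqrt(sum(q^2))
    # deterministic sign: first component of magnitude > 1e-8 made positive
    j <- which(abs(q) > 1e-8)[1L]
    if (!is.na(j) && q[j] < 0) q <- -q
    modes[i, , ] <- matrix(q, nrow = na, byrow = TRUE)
    kvec[i] <- drop(crossprod(q, hessian %*% q))
  }

  bad <- kvec <= 0
  if (any(bad)) {
    if (!allow_imaginary)
      stop("imaginary mode: ", sum(bad), " mode(s) with non-positive ",
           "force constant; pass allow_imaginary = TRUE to drop them")
    warning("dropping ", sum(bad), " imaginary mode(s)")
    modes <- modes[!bad, , , drop = FALSE]
    kvec <- kvec[!bad]
    lambda <- lambda[!bad]
  }

  structure(list(modes = modes, force_constants = kvec,
                 frequencies = mw_eigenvalue_to_cm1(lambda),
                 eigenvalues = lambda, projection_residual = residual,
                 reference = molecule, hessian = hessian, linear = linear),
            class = "nms_modes")
}

# Orthonormal basis of the rigid-body (translation + rotation) subspace in
# mass-weighted coordinates. Columns: up to 3 translations + 3 rotations;
# rank-deficient directions (linear molecules) are discarded by QR.
rigid_body_basis <- function(coords, masses, rank_tol = 1e-8) {
  na <- nrow(coords)
  n3 <- 3L * na
  sw <- sqrt(masses)
  com <- colSums(coords * masses) / sum(masses)
  r <- sweep(coords, 2L, com)
  b <- matrix(0, n3, 6L)
  for (a in 1:3) b[seq(a, n3, by = 3L), a] <- sw          # translations
  for (a in 1:3) {                                        # rotations e_a x r
    e <- diag(3L)[a, ]
    for (i in seq_len(na)) {
      b[(3L * (i - 1L) + 1L):(3L * i), 3L + a] <-
        sw[i] * c(e[2] * r[i, 3] - e[3] * r[i, 2],
                  e[3] * r[i, 1] - e[1] * r[i, 3],
                  e[1] * r[i, 2] - e[2] * r[i, 1])
    }
  }
  qrd <- qr(b, tol = rank_tol)
  qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
}

# mass-weighted eigenvalue (Ha / (amu A^2)) -> harmonic wavenumber (cm^-1);
# negative eigenvalues map to negative wavenumbers (reporting only)
mw_eigenvalue_to_cm1 <- function(lambda) {
  hartree_j <- 4.3597447222071e-18
  amu_kg <- 1.66053906660e-27
  ang_m <- 1e-10
  c_cm <- 2.99792458e10
  omega <- sqrt(abs(lambda) * hartree_j / (amu_kg * ang_m^2))
  sign(lambda) * omega / (2 * pi * c_cm)
}

#' @export
print.nms_modes <- function(x, ...) {
  cat(sprintf("<normal modes of %s: %d modes, K in [%.4g, %.4g] Ha/A^2%s>\n",
              x$reference$id, length(x$force_constants),
              min(x$force_constants), max(x$force_constants),
              if (x$linear) ", linear" else ""))
  invisible(x)
}

#' Read a Hessian from a plain-text matrix file
#'
#' Accepts either the full `3N x 3N` square (row-wise) or its lower triangle
#' (row-wise, diagonal included) as whitespace-delimited floats; `#` starts
#' a comment. Triangle input is mirrored to the full symmetric matrix.
#'
#' @param path Path to the text file.
#' @param n_atoms Number of atoms the Hessian belongs to.
#' @return A symmetric `3*n_atoms x 3*n_atoms` numeric matrix.
#' @export
read_hessian <- function(path, n_atoms) {
  n3 <- 3L * n_atoms
  vals <- scan(path, what = double(), comment.char = "#", quiet = TRUE)
  n_full <- n3 * n3
  n_tri <- n3 * (n3 + 1L) / 2L
  if (length(vals) == n_full) {
    h <- matrix(vals, n3, n3, byrow = TRUE)
  } else if (length(vals) == n_tri) {
    h <- matrix(0, n3, n3)
    h[upper.tri(h, diag = TRUE)] <- vals     # column-wise upper == row-wise lower
    h <- h + t(h) - diag(diag(h))
  } else {
    stop("expected ", n_full, " (full) or ", n_tri,
         " (lower triangle) values for ", n_atoms, " atoms, got ",
         length(vals))
  }
  (h + t(h)) / 2
}

#' Read externally computed modes and force constants
#'
#' Companion ingestion path for pipelines that already have normal modes:
#' `modes_path` holds `N_f` blocks of `N_a x 3` floats (whitespace-delimited,
#' blocks in mode order), `constants_path` holds `N_f` force constants
#' (Hartree/Angstrom^2). Modes are renormalized to unit Cartesian norm.
#'
#' @param modes_path,constants_path Paths to the two text files.
#' @param molecule Reference geometry the modes belong to.
#' @return An `nms_modes` object (without `hessian`; `frequencies` are `NA`).
#' @export
read_modes_files <- function(modes_path, constants_path, molecule) {
  na <- n_atoms(molecule)
  kvec <- scan(constants_path, what = double(), comment.char = "#", quiet = TRUE)
  nf <- length(kvec)
  if (any(kvec <= 0)) stop("force constants must be positive")
  vals <- scan(modes_path, what = double(), comment.char = "#", quiet = TRUE)
  if (length(vals) != nf * na * 3L)
    stop("expected ", nf * na * 3L, " mode components, got ", length(vals))
  modes <- array(0, dim = c(nf, na, 3L))
  for (i in seq_len(nf)) {
    block <- matrix(vals[((i - 1L) * na * 3L + 1L):(i * na * 3L)],
                    nrow = na, byrow = TRUE)
    modes[i, , ] <- block / sqrt(sum(block^2))
  }
  structure(list(modes = modes, force_constants = kvec,
                 frequencies = rep(NA_real_, nf),
                 eigenvalues = rep(NA_real_, nf),
                 projection_residual = NA_real_,
                 reference = molecule, hessian = NULL,
                 linear = detect_linearity(molecule)),
            class = "nms_modes")
}
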